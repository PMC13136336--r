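# Transfer-matrix serialization: Matrix Market dense-array files plus a
# YAML sidecar carrying provenance (mesh/electrode hashes, gauge tag).

write_mm_array <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("%%MatrixMarket matrix array real general", con)
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(formatC(as.numeric(m), format = "g", digits = 17), con)
  invisible(path)
}

read_mm_array <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("^%%MatrixMarket matrix array real", ln[1]))
    stopf("'%s' is not a MatrixMarket dense array file", path)
  ln <- ln[!grepl("^%", ln)]
  dims <- scan(text = ln[1], quiet = TRUE)
  vals <- as.numeric(ln[-1])
  matrix(vals, dims[1], dims[2])
}

#' Serialize a transfer operator as Matrix Market plus a YAML sidecar
#'
#' The matrix is written as a dense MatrixMarket array (`.mtx`) with 17
#' significant digits; a YAML sidecar (`<path>.yaml`) records the operator
#' kind, mesh and electrode hashes, the gauge tag and, for the volumetric
#' operator, the volume weights and heart node indices.
#'
#' @param transfer a `transfer_volumetric` or `transfer_epicardial`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_transfer_mtx <- function(transfer, path) {
  if (inherits(transfer, "transfer_volumetric")) {
    write_mm_array(transfer$B, path)
    meta <- list(kind = "volumetric", gauge = transfer$gauge,
                 singularity = transfer$singularity,
                 mesh_hash = transfer$mesh_hash,
                 electrode_hash = transfer$electrode_hash,
                 heart_nodes = as.integer(transfer$heart_nodes),
                 weights = as.numeric(transfer$weights))
  } else if (inherits(transfer, "transfer_epicardial")) {
    write_mm_array(transfer$A, path)
    meta <- list(kind = "epicardial",
                 mesh_hash = transfer$mesh_hash,
                 electrode_hash = transfer$electrode_hash,
                 n_torso = transfer$n_torso, n_heart = transfer$n_heart)
  } else stopf("unsupported transfer object")
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 17L)
  invisible(path)
}

#' Read a serialized transfer operator
#'
#' @param path `.mtx` path written by [write_transfer_mtx()] (the YAML
#'   sidecar must sit next to it).
#' @return a `transfer_volumetric` or `transfer_epicardial` object.
#' @export
read_transfer_mtx <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- read_mm_array(path)
  if (identical(meta$kind, "volumetric")) {
    structure(list(B = m,
                   weights = structure(as.numeric(meta$weights),
                                       nodes = as.integer(meta$heart_nodes),
                                       class = "volume_weights"),
                   heart_nodes = as.integer(meta$heart_nodes),
                   gauge = meta$gauge, singularity = meta$singularity,
                   n_solves = nrow(m),
                   mesh_hash = meta$mesh_hash,
                   electrode_hash = meta$electrode_hash),
              class = "transfer_volumetric")
  } else if (identical(meta$kind, "epicardial")) {
    structure(list(A = m, A_full = NULL,
                   n_torso = meta$n_torso, n_heart = meta$n_heart,
                   mesh_hash = meta$mesh_hash,
                   electrode_hash = meta$electrode_hash),
              class = "transfer_epicardial")
  } else stopf("sidecar of '%s' has unknown kind", path)
}
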