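#' Construct a plate of Ct values
#'
#' A `scx_plate` holds one chip/run: a wells x genes matrix of cycle-threshold
#' values, a parallel detection mask, and the limit of detection (LOD, the
#' maximum number of PCR cycles run). Ct is finite wherever `detected` is
#' `TRUE`; not-detected entries carry `NA` Ct.
#'
#' @param plate_id single string identifying the run.
#' @param wells character vector of well IDs or opaque cell labels (row names).
#' @param genes character vector of gene names (column names).
#' @param ct numeric wells x genes matrix of Ct cycles; `NA` where not detected.
#' @param detected logical matrix of the same shape; defaults to `!is.na(ct)`.
#' @param lod limit of detection in cycles (default 40).
#' @return an object of class `scx_plate`.
#' @export
scx_plate <- function(plate_id, wells, genes, ct, detected = NULL, lod = 40) {
  wells <- as.character(wells); genes <- as.character(genes)
  ct <- as.matrix(ct)
  if (anyDuplicated(wells)) {
    stop("duplicate wells on plate '", plate_id, "': ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes))
    stop("duplicate genes on plate '", plate_id, "'", call. = FALSE)
  if (!isTRUE(nrow(ct) == length(wells)) || !isTRUE(ncol(ct) == length(genes)))
    stop("ct matrix dimensions do not match wells x genes", call. = FALSE)
  if (is.null(detected)) detected <- !is.na(ct)
  detected <- as.matrix(detected)
  storage.mode(ct) <- "double"
  if (!is.logical(detected) || !all(dim(detected) == dim(ct)))
    stop("detected mask must be a logical matrix matching ct", call. = FALSE)
  if (any(detected & !is.finite(ct)))
    stop("ct must be finite wherever detected", call. = FALSE)
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0)
    stop("lod must be a single positive number of cycles", call. = FALSE)
  # Ct beyond the maximum cycle count carries no quantitative information
  over <- detected & ct > lod
  ct[over] <- lod
  ct[!detected] <- NA_real_
  dimnames(ct) <- dimnames(detected) <- list(wells, genes)
  structure(list(plate_id = as.character(plate_id), wells = wells,
                 genes = genes, ct = ct, detected = detected, lod = lod),
            class = "scx_plate")
}

#' @export
print.scx_plate <- function(x, ...) {
  cat("scx_plate '", x$plate_id, "': ", length(x$wells), " wells x ",
      length(x$genes), " genes, LOD ", x$lod, " cycles, ",
      sum(x$detected), " detected entries\n", sep = "")
  invisible(x)
}

#' @export
dim.scx_plate <- function(x) c(length(x$wells), length(x$genes))
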