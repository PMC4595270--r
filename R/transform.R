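# Scale conversion and normalisation. Ct counts cycles-to-threshold, so
# lower Ct = more transcript; inversion (LOD - Ct) puts the data on an
# intuitive "bigger is more" scale with 0 at the detection floor. The
# optional housekeeping step is an additive shift on the cycle scale
# (multiplicative in linear expression space), and the z-transform
# standardises per gene (default) or per cell.

#' Invert Ct values against the limit of detection
#'
#' Detected entries become `lod - ct`, clamped at 0 for supra-LOD Ct;
#' not-detected entries become 0 (equivalent to imputing Ct = LOD: no
#' detection by the final cycle means expression at or below the floor).
#'
#' @param exp an `scx_experiment` at stage `raw_ct`.
#' @param lod limit of detection in cycles; defaults to the experiment's LOD.
#' @return the experiment at stage `inverted`.
#' @export
invert_ct <- function(exp, lod = exp$lod) {
  assert_stage(exp, "raw_ct", "invert_ct")
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0)
    stop("lod must be a single positive number of cycles", call. = FALSE)
  m <- exp$matrix
  inv <- pmax(lod - m, 0)
  inv[!exp$detected] <- 0
  if (all(inv == 0) && length(inv) > 0L)
    warning("LOD at or below all observed Ct: all inverted values are 0",
            call. = FALSE)
  exp$matrix <- inv
  exp$lod <- lod
  exp$stage <- "inverted"
  log_append(exp, "invert_ct", params = list(lod = lod),
             counts = list(n_zero = sum(inv == 0)))
}

#' Housekeeping-median normalisation
#'
#' Shifts every value in cell c by `M - m_c`, where `m_c` is the median of
#' the cell's detected housekeeping values and `M` the median of the `m_c`
#' over cells. Afterwards each cell's housekeeping median equals `M` exactly,
#' and within-cell gene differences are unchanged. Cells with no detected
#' housekeeping gene are left unshifted and flagged.
#'
#' @param exp an `scx_experiment` at stage `raw_ct` or `inverted`.
#' @param hk_genes character vector of housekeeping genes on the panel.
#' @return the experiment at stage `hk_normalised`.
#' @export
normalize_housekeeping <- function(exp, hk_genes) {
  assert_stage(exp, c("raw_ct", "inverted"), "normalize_housekeeping")
  if (length(hk_genes) < 1L) stop("no housekeeping gene supplied", call. = FALSE)
  unknown <- setdiff(hk_genes, exp$genes)
  if (length(unknown) > 0L)
    stop("housekeeping gene(s) not on panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hk <- exp$matrix[, hk_genes, drop = FALSE]
  hk_det <- exp$detected[, hk_genes, drop = FALSE]
  hk[!hk_det] <- NA_real_
  m_c <- apply(hk, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
  M <- stats::median(m_c, na.rm = TRUE)
  shift <- M - m_c
  unshifted <- is.na(shift)
  shift[unshifted] <- 0
  exp$matrix <- exp$matrix + shift            # recycles column-wise by cell
  if (any(unshifted)) {
    exp$flags <- c(exp$flags,
                   paste0("no detected housekeeping gene; cell left unshifted: ",
                          paste(exp$cells[unshifted], collapse = ", ")))
  }
  exp$stage <- "hk_normalised"
  log_append(exp, "normalize_housekeeping",
             params = list(hk_genes = hk_genes, reference_median = M),
             counts = list(n_unshifted = sum(unshifted)))
}

#' z-transform expression profiles
#'
#' Along the chosen axis, subtract the mean and divide by the standard
#' deviation. Zero-variance vectors map to all zeros with a warning rather
#' than erroring (all-dropout genes should stay visible downstream).
#'
#' @param exp an `scx_experiment` at stage `inverted` or `hk_normalised`.
#' @param axis `"per_gene"` (default: each gene standardised over cells) or
#'   `"per_cell"`.
#' @param denominator `"sample"` (default, n-1) or `"population"` (n).
#' @return the experiment at stage `z_transformed`.
#' @export
z_transform <- function(exp, axis = c("per_gene", "per_cell"),
                        denominator = c("sample", "population")) {
  assert_stage(exp, c("inverted", "hk_normalised"), "z_transform")
  axis <- match.arg(axis); denominator <- match.arg(denominator)
  zfun <- function(v) {
    mu <- mean(v)
    s <- stats::sd(v)
    if (denominator == "population") s <- s * sqrt((length(v) - 1) / length(v))
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mu) / s
  }
  m <- exp$matrix
  if (axis == "per_gene") {
    const <- apply(m, 2, function(v) stats::sd(v) == 0)
    z <- apply(m, 2, zfun)
  } else {
    const <- apply(m, 1, function(v) stats::sd(v) == 0)
    z <- t(apply(m, 1, zfun))
  }
  if (any(const))
    warning(sum(const), " zero-variance ",
            if (axis == "per_gene") "gene(s)" else "cell(s)",
            " mapped to all-zeros", call. = FALSE)
  dimnames(z) <- dimnames(exp$matrix)
  exp$matrix <- z
  exp$stage <- "z_transformed"
  log_append(exp, "z_transform",
             params = list(axis = axis, denominator = denominator),
             counts = list(n_constant = sum(const)))
}
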