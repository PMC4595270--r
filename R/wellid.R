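#' Canonicalise a plate well identifier
#'
#' Well IDs are the join key between expression plates and index-sorting
#' tables, so every reader funnels labels through this function. The
#' canonical form is an upper-case row letter followed by a zero-padded
#' two-digit column, e.g. `"A01"`.
#'
#' @param raw character vector of well labels (e.g. `"a1"`, `"H12"`).
#' @param plate_format `96` (rows A-H, columns 1-12) or `384` (A-P, 1-24).
#' @return character vector of canonical well IDs.
#' @examples
#' normalize_well_id(c("A1", "h12"))        # "A01" "H12"
#' @export
normalize_well_id <- function(raw, plate_format = 96) {
  if (!plate_format %in% c(96L, 384L))
    stop("plate_format must be 96 or 384", call. = FALSE)
  raw_chr <- as.character(raw)
  if (length(raw_chr) == 0L || any(is.na(raw_chr)) || any(!nzchar(trimws(raw_chr))))
    stop("well ID must be non-empty", call. = FALSE)
  x <- toupper(trimws(raw_chr))
  m <- regmatches(x, regexec("^([A-Z])0*([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed well ID: ", paste(unique(raw_chr[bad]), collapse = ", "),
         call. = FALSE)
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  max_row <- if (plate_format == 96L) "H" else "P"
  max_col <- if (plate_format == 96L) 12L else 24L
  oob <- row > max_row | col < 1L | col > max_col
  if (any(oob))
    stop("well ID out of range for ", plate_format, "-well plate: ",
         paste(unique(raw_chr[oob]), collapse = ", "), call. = FALSE)
  sprintf("%s%02d", row, col)
}

#' Test whether labels parse as well IDs
#'
#' @param x character vector.
#' @param plate_format `96` or `384`.
#' @return logical vector.
#' @export
is_well_id <- function(x, plate_format = 96) {
  vapply(as.character(x), function(lab) {
    if (is.na(lab) || !nzchar(trimws(lab))) return(FALSE)
    !inherits(tryCatch(normalize_well_id(lab, plate_format),
                       error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}

# cell IDs are plate-qualified so that multiple runs never collide
make_cell_id <- function(plate_id, well) paste0(plate_id, ":", well)

split_cell_id <- function(cell_id) {
  pos <- regexpr(":", cell_id, fixed = TRUE)
  if (any(pos < 0)) stop("malformed cell ID: ", cell_id[pos < 0][1], call. = FALSE)
  list(plate_id = substr(cell_id, 1L, pos - 1L),
       well = substr(cell_id, pos + 1L, nchar(cell_id)))
}
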