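# Readers for the three expression input dialects plus index-sorting tables.
# Non-detect convention (shared by all readers): Ct sentinel 999, a blank cell,
# a declared missing token ("NA", "" by default) or a "Fail" quality call all
# mark the entry as not detected.

#' Describe a Biomark-style export dialect
#'
#' The exact column naming of chip exports varies between software versions,
#' so the table reader is driven by a dialect description. Defaults match the
#' common long-format export: one row per chamber with well, gene, Ct and a
#' Pass/Fail call; delimiter auto-detected among tab and comma; leading
#' banner lines skipped until a header containing the Ct column is found.
#'
#' @param well_col,gene_col,ct_col,call_col header names (matched
#'   case-insensitively). `call_col` may be `NA` if the export has no call
#'   column.
#' @param delim field delimiter, or `NA` to auto-detect tab vs comma.
#' @param fail_call value of the call column marking a failed chamber.
#' @param missing_tokens values (besides the 999 sentinel) read as not-detected.
#' @param sentinel numeric Ct sentinel for "no amplification".
#' @return a list of class `scx_dialect`.
#' @export
biomark_dialect <- function(well_col = "Well", gene_col = "Gene",
                            ct_col = "Ct", call_col = "Call",
                            delim = NA, fail_call = "Fail",
                            missing_tokens = c("NA", ""), sentinel = 999) {
  structure(list(well_col = well_col, gene_col = gene_col, ct_col = ct_col,
                 call_col = call_col, delim = delim, fail_call = fail_call,
                 missing_tokens = missing_tokens, sentinel = sentinel),
            class = "scx_dialect")
}

detect_delim <- function(lines) {
  n_tab <- sum(vapply(lines, function(l) lengths(regmatches(l, gregexpr("\t", l))), 1L))
  n_com <- sum(vapply(lines, function(l) lengths(regmatches(l, gregexpr(",", l))), 1L))
  if (n_tab >= n_com) "\t" else ","
}

split_fields <- function(line, delim) {
  # sentinel preserves trailing empty fields, which strsplit would drop
  out <- strsplit(paste0(line, delim, "\x01"), delim, fixed = TRUE)[[1]]
  out <- out[-length(out)]
  trimws(gsub('^"|"$', "", out))
}

parse_ct_token <- function(tok, dialect) {
  tok <- trimws(tok)
  if (tok %in% dialect$missing_tokens) return(NA_real_)
  val <- suppressWarnings(as.numeric(tok))
  if (is.na(val)) stop("unparseable Ct value: '", tok, "'", call. = FALSE)
  if (val == dialect$sentinel) NA_real_ else val
}

#' Read a Biomark-style long-format ("table") export
#'
#' One row per (well, gene) chamber. Rows whose call equals the dialect's
#' fail value, or whose Ct is the 999 sentinel, are recorded as not detected.
#'
#' @param path file path.
#' @param dialect a [biomark_dialect()] description.
#' @param plate_id plate identifier; defaults to the file base name.
#' @param lod limit of detection in cycles.
#' @param plate_format 96 or 384, for well canonicalisation.
#' @return an [scx_plate()].
#' @export
read_biomark_table <- function(path, dialect = biomark_dialect(),
                               plate_id = NULL, lod = 40, plate_format = 96) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]+$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- if (is.na(dialect$delim)) detect_delim(utils::head(lines, 30)) else dialect$delim
  # skip banner lines until a header mentioning the Ct column
  hdr_idx <- which(vapply(lines, function(l) {
    any(tolower(split_fields(l, delim)) == tolower(dialect$ct_col))
  }, logical(1)))[1]
  if (is.na(hdr_idx))
    stop("missing mandatory column '", dialect$ct_col, "' in ", path, call. = FALSE)
  header <- split_fields(lines[hdr_idx], delim)
  find_col <- function(name, required = TRUE) {
    i <- which(tolower(header) == tolower(name))[1]
    if (is.na(i) && required)
      stop("missing mandatory column '", name, "' in ", path, call. = FALSE)
    i
  }
  wi <- find_col(dialect$well_col); gi <- find_col(dialect$gene_col)
  ci <- find_col(dialect$ct_col)
  li <- if (is.na(dialect$call_col) || is.null(dialect$call_col)) NA_integer_
        else find_col(dialect$call_col, required = FALSE)
  body <- lines[-seq_len(hdr_idx)]
  recs <- lapply(body, split_fields, delim = delim)
  wells_raw <- vapply(recs, `[`, "", wi)
  wells <- normalize_well_id(wells_raw, plate_format)
  genes_raw <- vapply(recs, `[`, "", gi)
  key <- paste(wells, genes_raw, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (well, gene) row: ", gsub("\r", "/", d), call. = FALSE)
  }
  ct_val <- vapply(vapply(recs, `[`, "", ci), parse_ct_token, 0,
                   dialect = dialect, USE.NAMES = FALSE)
  det <- !is.na(ct_val)
  if (!is.na(li)) {
    calls <- vapply(recs, `[`, "", li)
    det <- det & !(tolower(calls) == tolower(dialect$fail_call))
  }
  u_wells <- unique(wells); u_genes <- unique(genes_raw)
  ct <- matrix(NA_real_, length(u_wells), length(u_genes),
               dimnames = list(u_wells, u_genes))
  dm <- matrix(FALSE, length(u_wells), length(u_genes),
               dimnames = list(u_wells, u_genes))
  idx <- cbind(match(wells, u_wells), match(genes_raw, u_genes))
  ct[idx] <- ifelse(det, ct_val, NA_real_)
  dm[idx] <- det
  scx_plate(plate_id, u_wells, u_genes, ct, dm, lod)
}

#' Read a Biomark-style grid ("heatmap") export
#'
#' Rectangular layout: first row gene names, first column well IDs, one Ct per
#' cell. 999 sentinels and blank cells are not-detected.
#'
#' @inheritParams read_biomark_table
#' @return an [scx_plate()].
#' @export
read_biomark_heatmap <- function(path, dialect = biomark_dialect(),
                                 plate_id = NULL, lod = 40, plate_format = 96) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]+$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- if (is.na(dialect$delim)) detect_delim(utils::head(lines, 5)) else dialect$delim
  header <- split_fields(lines[1], delim)
  genes <- header[-1]
  n <- length(genes)
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- split_fields(lines[i], delim)
    if (length(f) != n + 1L)
      stop("ragged row ", i, ": expected ", n + 1L, " fields, got ",
           length(f), call. = FALSE)
    f
  })
  wells <- normalize_well_id(vapply(rows, `[`, "", 1L), plate_format)
  if (anyDuplicated(wells))
    stop("duplicate well rows: ", wells[duplicated(wells)][1], call. = FALSE)
  ct <- t(vapply(rows, function(f)
    vapply(f[-1], parse_ct_token, 0, dialect = dialect, USE.NAMES = FALSE),
    numeric(n)))
  scx_plate(plate_id, wells, genes, ct, lod = lod)
}

#' Read a generic cells x genes Ct matrix (tab-delimited)
#'
#' First row gene names, first column cell labels. Labels that parse as well
#' IDs are canonicalised; any other label is kept verbatim as an opaque cell
#' label (such cells cannot be joined to index-sorting data).
#'
#' @param path file path.
#' @param plate_id plate identifier; defaults to the file base name.
#' @param lod limit of detection in cycles.
#' @param missing_tokens values read as not-detected (besides the 999 sentinel).
#' @param plate_format 96 or 384.
#' @return an [scx_plate()].
#' @export
read_ct_matrix <- function(path, plate_id = NULL, lod = 40,
                           missing_tokens = c("NA", ""), plate_format = 96) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]+$", "", basename(path))
  dialect <- biomark_dialect(delim = "\t", missing_tokens = missing_tokens)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- split_fields(lines[1], "\t")
  genes <- header[-1]
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- split_fields(lines[i], "\t")
    if (length(f) != length(genes) + 1L)
      stop("ragged row ", i, " in ", path, call. = FALSE)
    f
  })
  labels <- vapply(rows, `[`, "", 1L)
  wellish <- is_well_id(labels, plate_format)
  labels[wellish] <- normalize_well_id(labels[wellish], plate_format)
  if (anyDuplicated(labels))
    stop("duplicate cell labels: ", labels[duplicated(labels)][1], call. = FALSE)
  ct <- t(vapply(rows, function(f)
    vapply(f[-1], parse_ct_token, 0, dialect = dialect, USE.NAMES = FALSE),
    numeric(length(genes))))
  scx_plate(plate_id, labels, genes, ct, lod = lod)
}

#' Read an index-sorting intensity table
#'
#' Tab-delimited: one column of well IDs (identified by header name "Well"
#' or, failing that, the first column whose values all parse as well IDs),
#' remaining numeric columns are surface-marker / scatter-channel intensities.
#' Negative intensities are valid (post-compensation fluorescence) and kept.
#'
#' @param path file path.
#' @param plate_id optional plate identifier used when joining multi-plate
#'   experiments; defaults to `NA` (resolvable only in single-plate joins).
#' @param plate_format 96 or 384.
#' @return a list of class `scx_index` with `wells`, `markers`, `intensity`
#'   (wells x markers matrix) and `plate_id`.
#' @export
read_index_table <- function(path, plate_id = NA_character_, plate_format = 96) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("index table needs a well column plus markers", call. = FALSE)
  wi <- which(tolower(names(df)) %in% c("well", "well id", "well_id"))[1]
  if (is.na(wi)) {
    cand <- which(vapply(df, function(col) all(is_well_id(col, plate_format)), logical(1)))
    if (length(cand) == 0L)
      stop("no well-ID column found in ", path, call. = FALSE)
    wi <- cand[1]
  }
  wells <- normalize_well_id(as.character(df[[wi]]), plate_format)
  if (anyDuplicated(wells))
    stop("duplicate wells in index table: ",
         wells[duplicated(wells)][1], call. = FALSE)
  markers <- names(df)[-wi]
  if (any(!nzchar(markers)) || anyDuplicated(markers))
    stop("marker names must be non-empty and unique", call. = FALSE)
  intensity <- as.matrix(df[, -wi, drop = FALSE])
  storage.mode(intensity) <- "double"
  dimnames(intensity) <- list(wells, markers)
  structure(list(wells = wells, markers = markers, intensity = intensity,
                 plate_id = plate_id),
            class = "scx_index")
}
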