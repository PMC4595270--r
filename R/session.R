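# Session persistence. A session archive is a ZIP file holding the full
# experiment (matrices as TSV at 17 significant digits, which round-trips
# IEEE doubles exactly), the grouping, the analysis log, the scrapbook and a
# manifest. load(save(x)) is an exact fixed point.
#
# The archive is written with a small pure-R ZIP writer (STORE method, no
# compression) because the target environment ships `unzip` but no `zip`
# binary; reading uses R's internal unzip.

SESSION_FORMAT_VERSION <- "1.0"

# ---- minimal ZIP writer ----------------------------------------------------

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320 as signed int
      else bitwShiftR(c, 1)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8), crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32 <- function(x) {
  if (x > 2147483647) x <- x - 4294967296    # two's complement for writeBin
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

# fixed DOS timestamp so identical content yields identical archives
DOS_TIME <- bitwOr(bitwShiftL(12L, 11), 0L)            # 12:00:00
DOS_DATE <- bitwOr(bitwOr(bitwShiftL(2015L - 1980L, 9), bitwShiftL(10L, 5)), 5L)

write_zip <- function(zipfile, members) {
  # members: named list of raw vectors (names are archive paths)
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- integer(length(members))
  crcs <- integer(length(members))
  pos <- 0L
  for (i in seq_along(members)) {
    name <- charToRaw(names(members)[i])
    data <- members[[i]]
    crc <- crc32(data)
    crcs[i] <- crc
    offsets[i] <- pos
    crc_u <- if (crc < 0) crc + 4294967296 else crc
    hdr <- c(uint32(0x04034b50), uint16(20), uint16(0), uint16(0),
             uint16(DOS_TIME), uint16(DOS_DATE), uint32(crc_u),
             uint32(length(data)), uint32(length(data)),
             uint16(length(name)), uint16(0))
    writeBin(hdr, con); writeBin(name, con); writeBin(data, con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(members)) {
    name <- charToRaw(names(members)[i])
    data <- members[[i]]
    crc_u <- if (crcs[i] < 0) crcs[i] + 4294967296 else crcs[i]
    cd <- c(uint32(0x02014b50), uint16(20), uint16(20), uint16(0), uint16(0),
            uint16(DOS_TIME), uint16(DOS_DATE), uint32(crc_u),
            uint32(length(data)), uint32(length(data)),
            uint16(length(name)), uint16(0), uint16(0), uint16(0), uint16(0),
            uint32(0), uint32(offsets[i]))
    writeBin(cd, con); writeBin(name, con)
    pos <- pos + length(cd) + length(name)
  }
  eocd <- c(uint32(0x06054b50), uint16(0), uint16(0),
            uint16(length(members)), uint16(length(members)),
            uint32(pos - cd_start), uint32(cd_start), uint16(0))
  writeBin(eocd, con)
  invisible(zipfile)
}

# ---- matrix <-> TSV with exact double round-trip ---------------------------

format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

matrix_to_tsv <- function(m) {
  header <- paste(c("", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t"), "")
  paste(c(header, body, ""), collapse = "\n")
}

tsv_to_matrix <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  if (length(lines) == 1L)
    return(matrix(numeric(), 0, length(header),
                  dimnames = list(character(), header)))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rn <- vapply(rows, `[`, "", 1L)
  m <- t(vapply(rows, function(f) {
    v <- f[-1]
    out <- suppressWarnings(as.numeric(v))
    out[v == "NA"] <- NA_real_
    out
  }, numeric(length(header))))
  if (length(header) == 1L) m <- matrix(m, ncol = 1L)
  dimnames(m) <- list(rn, header)
  m
}

logical_to_tsv <- function(m) {
  storage.mode(m) <- "double"      # keeps dims even for 0-row matrices
  matrix_to_tsv(m)
}

# ---- save / load -----------------------------------------------------------

#' Save a session to a ZIP archive
#'
#' The archive holds the manifest, all matrices (TSV, exact double
#' round-trip), the grouping, the analysis log, and the scrapbook with its
#' figure files. `load_session(save_session(x))` reproduces `x` exactly.
#'
#' @param state a session state: list with `experiment` (`scx_experiment`),
#'   `scrapbook` (optional) and `config` (optional snapshot).
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
save_session <- function(state, path) {
  if (inherits(state, "scx_experiment"))
    state <- list(experiment = state, scrapbook = new_scrapbook(), config = NULL)
  exp <- state$experiment
  sb <- if (is.null(state$scrapbook)) new_scrapbook() else state$scrapbook
  manifest <- list(format_version = SESSION_FORMAT_VERSION,
                   stage = exp$stage, lod = exp$lod,
                   n_cells = length(exp$cells), n_genes = length(exp$genes),
                   flags = exp$flags,
                   config = state$config)
  members <- list()
  members[["manifest.json"]] <-
    charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                               null = "null", pretty = TRUE))
  cells_tsv <- paste(c("cell_id\tplate_id\twell",
                       paste(exp$cells, exp$plates, exp$wells, sep = "\t"), ""),
                     collapse = "\n")
  members[["cells.tsv"]] <- charToRaw(cells_tsv)
  members[["matrix.tsv"]] <- charToRaw(matrix_to_tsv(exp$matrix))
  members[["detected.tsv"]] <- charToRaw(logical_to_tsv(exp$detected))
  if (!is.null(exp$index))
    members[["index_markers.tsv"]] <- charToRaw(matrix_to_tsv(exp$index$matrix))
  if (!is.null(exp$grouping))
    members[["grouping.json"]] <-
      charToRaw(jsonlite::toJSON(unclass(exp$grouping), auto_unbox = TRUE,
                                 digits = NA, pretty = TRUE))
  members[["log.json"]] <-
    charToRaw(jsonlite::toJSON(exp$log, auto_unbox = TRUE, digits = NA,
                               null = "null", pretty = TRUE))
  members[["scrapbook/annotations.json"]] <-
    charToRaw(jsonlite::toJSON(sb$entries, auto_unbox = TRUE, null = "null",
                               pretty = TRUE))
  for (e in sb$entries) {
    if (!is.null(e$figure) && !is.na(e$figure) && file.exists(e$figure)) {
      members[[paste0("scrapbook/", basename(e$figure))]] <-
        readBin(e$figure, "raw", file.size(e$figure))
    }
  }
  write_zip(path, members)
  invisible(path)
}

read_member <- function(dir, name, required = TRUE) {
  f <- file.path(dir, name)
  if (!file.exists(f)) {
    if (required) stop("corrupted archive: missing member '", name, "'",
                       call. = FALSE)
    return(NULL)
  }
  readChar(f, file.size(f), useBytes = TRUE)
}

#' Load a session from a ZIP archive
#'
#' @param path archive written by [save_session()].
#' @return a session state: list with `experiment`, `scrapbook`, `config`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dir <- tempfile("scx_session_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::unzip(path, exdir = dir)
  manifest_txt <- read_member(dir, "manifest.json")
  manifest <- jsonlite::fromJSON(manifest_txt, simplifyVector = TRUE)
  if (!identical(manifest$format_version, SESSION_FORMAT_VERSION))
    stop("session format version mismatch: archive has '",
         manifest$format_version, "', expected '", SESSION_FORMAT_VERSION, "'",
         call. = FALSE)
  cells_txt <- read_member(dir, "cells.tsv")
  clines <- strsplit(cells_txt, "\n", fixed = TRUE)[[1]]
  clines <- clines[nzchar(clines)][-1]
  cfields <- strsplit(clines, "\t", fixed = TRUE)
  cells <- vapply(cfields, `[`, "", 1L)
  plates <- vapply(cfields, `[`, "", 2L)
  wells <- vapply(cfields, `[`, "", 3L)
  mat <- tsv_to_matrix(read_member(dir, "matrix.tsv"))
  det_num <- tsv_to_matrix(read_member(dir, "detected.tsv"))
  det <- det_num == 1                       # keeps dims/dimnames, 0-row safe
  idx_txt <- read_member(dir, "index_markers.tsv", required = FALSE)
  index <- NULL
  if (!is.null(idx_txt)) {
    im <- tsv_to_matrix(idx_txt)
    index <- list(markers = colnames(im), matrix = im)
  }
  grp_txt <- read_member(dir, "grouping.json", required = FALSE)
  grouping <- NULL
  if (!is.null(grp_txt)) {
    g <- jsonlite::fromJSON(grp_txt, simplifyVector = TRUE)
    members <- g$members
    if (!is.list(members)) members <- apply(members, 1, identity, simplify = FALSE)
    members <- lapply(members, as.character)
    grouping <- new_grouping(g$labels, g$colors, members, g$source)
  }
  # scalar arrays come back as vectors, objects as lists, so re-serialising
  # the log reproduces the archive byte-for-byte
  log_raw <- jsonlite::fromJSON(read_member(dir, "log.json"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  log <- lapply(log_raw, function(e) { e$seq <- as.integer(e$seq); e })
  flags <- as.character(unlist(manifest$flags))
  exp <- new_experiment(cells, plates, wells, colnames(mat), mat, det,
                        manifest$stage, as.numeric(manifest$lod), index = index,
                        grouping = grouping, log = log, flags = flags)
  sb_txt <- read_member(dir, "scrapbook/annotations.json", required = FALSE)
  sb <- new_scrapbook()
  if (!is.null(sb_txt)) {
    entries <- jsonlite::fromJSON(sb_txt, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
    sb$entries <- lapply(entries, function(e) {
      e$seq <- as.integer(e$seq)
      if (is.null(e$figure)) e$figure <- NA_character_
      e
    })
  }
  config <- manifest$config
  list(experiment = exp, scrapbook = sb, config = config)
}
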