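#' Read a morphological matrix from a NEXUS file
#'
#' Parses a DATA or CHARACTERS block (interleaved or not) with standard
#' datatype symbols 0-9, `missing` and `gap` declarations, plus an optional
#' SETS block whose `charset` definitions become partition labels and whose
#' `taxset fossil` / `taxset outgroup` definitions become taxon classes.
#'
#' `"?"` cells map to missing, gap (`"-"`) cells to inapplicable, and
#' parenthesized or braced multi-digit cells, e.g. `(01)` or `{01}`, to
#' polymorphic state sets.
#'
#' @param path path to a NEXUS file.
#' @return A [char_matrix].
#' @export
read_nexus_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- strip_nexus_comments(paste(txt, collapse = "\n"))
  if (!grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header): ", path)

  blocks <- nexus_blocks(txt)
  datablock <- blocks[["data"]]
  if (is.null(datablock)) datablock <- blocks[["characters"]]
  if (is.null(datablock)) stop("no DATA or CHARACTERS block in ", path)

  dims <- nexus_command(datablock, "dimensions")
  ntax <- as.integer(nexus_kv(dims, "ntax"))
  nchar_ <- as.integer(nexus_kv(dims, "nchar"))
  if (is.na(ntax) || is.na(nchar_)) stop("DIMENSIONS must declare NTAX and NCHAR")

  fmt <- nexus_command(datablock, "format")
  missing_sym <- nexus_kv(fmt, "missing"); if (is.na(missing_sym)) missing_sym <- "?"
  gap_sym <- nexus_kv(fmt, "gap"); if (is.na(gap_sym)) gap_sym <- "-"
  interleave <- grepl("interleave", fmt, ignore.case = TRUE)

  mtx <- nexus_command(datablock, "matrix", body = TRUE)
  rows <- strsplit(mtx, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]

  taxa <- character(0)
  cells <- list()
  for (ln in rows) {
    m <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(\\S.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed matrix row: '", ln, "'")
    lab <- gsub("^['\"]|['\"]$", "", m[2])
    seqtxt <- gsub("\\s", "", m[3])
    toks <- tokenize_cells(seqtxt, missing_sym, gap_sym, ln)
    if (lab %in% taxa) {
      if (!interleave) stop("duplicate taxon label: ", lab)
      cells[[lab]] <- c(cells[[lab]], toks)
    } else {
      taxa <- c(taxa, lab)
      cells[[lab]] <- toks
    }
  }
  if (length(taxa) != ntax)
    stop("NTAX=", ntax, " but matrix has ", length(taxa), " taxa")
  nc <- vapply(cells, length, integer(1))
  if (any(nc != nchar_))
    stop("cell count mismatch for taxon '", taxa[which(nc != nchar_)[1]],
         "': got ", nc[which(nc != nchar_)[1]], ", expected ", nchar_)

  cellmat <- do.call(rbind, cells[taxa])
  rownames(cellmat) <- taxa

  partition <- rep("all", nchar_)
  taxon_class <- NULL
  sets <- blocks[["sets"]]
  if (!is.null(sets)) {
    for (cs in nexus_commands(sets, "charset")) {
      m <- regmatches(cs, regexec("^\\s*(\\S+)\\s*=\\s*(.*)$", cs))[[1]]
      if (length(m) != 3) stop("malformed charset: ", cs)
      partition[parse_nexus_range(m[3], nchar_)] <- m[2]
    }
    for (ts in nexus_commands(sets, "taxset")) {
      m <- regmatches(ts, regexec("^\\s*(\\S+)\\s*=\\s*(.*)$", ts))[[1]]
      if (length(m) != 3) stop("malformed taxset: ", ts)
      cls <- tolower(m[2])
      if (cls %in% c("fossil", "outgroup", "extant")) {
        members <- strsplit(trimws(m[3]), "\\s+")[[1]]
        members <- gsub("^['\"]|['\"]$", "", members)
        tc <- rep(cls, length(members))
        names(tc) <- members
        taxon_class <- c(taxon_class, tc)
      }
    }
  }
  char_matrix(cellmat, taxa = taxa, partition = partition,
              taxon_class = taxon_class)
}

tokenize_cells <- function(s, missing_sym, gap_sym, where) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i + 1
      states <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        states <- c(states, chars[j]); j <- j + 1
      }
      if (j > length(chars)) stop("unclosed polymorphism in row: ", where)
      out <- c(out, paste(states, collapse = ""))
      i <- j + 1
    } else if (ch == missing_sym) {
      out <- c(out, "?"); i <- i + 1
    } else if (ch == gap_sym || ch == "−") {
      out <- c(out, "-"); i <- i + 1
    } else {
      out <- c(out, ch); i <- i + 1
    }
  }
  out
}

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

nexus_blocks <- function(txt) {
  # returns named list of block bodies, lower-cased names
  pat <- gregexpr("(?is)begin\\s+(\\w+)\\s*;(.*?)end\\s*;", txt, perl = TRUE)
  m <- regmatches(txt, pat)[[1]]
  out <- list()
  for (blk in m) {
    name <- tolower(sub("(?is)^begin\\s+(\\w+).*", "\\1", blk, perl = TRUE))
    body <- sub("(?is)^begin\\s+\\w+\\s*;", "", blk, perl = TRUE)
    body <- sub("(?is)end\\s*;\\s*$", "", body, perl = TRUE)
    out[[name]] <- body
  }
  out
}

# first command of a given name; body=TRUE returns everything up to the
# terminating semicolon (for MATRIX)
nexus_command <- function(block, name, body = FALSE) {
  pat <- paste0("(?is)\\b", name, "\\b(.*?);")
  m <- regmatches(block, regexpr(pat, block, perl = TRUE))
  if (!length(m)) {
    if (body) stop("missing ", toupper(name), " command")
    return("")
  }
  res <- sub(paste0("(?is)^.*?\\b", name, "\\b"), "", m, perl = TRUE)
  sub(";\\s*$", "", res)
}

nexus_commands <- function(block, name) {
  pat <- paste0("(?is)\\b", name, "\\b\\s*(.*?);")
  m <- gregexpr(pat, block, perl = TRUE)
  hits <- regmatches(block, m)[[1]]
  vapply(hits, function(h) {
    h <- sub(paste0("(?is)^\\s*", name, "\\b"), "", h, perl = TRUE)
    trimws(sub(";\\s*$", "", h))
  }, character(1), USE.NAMES = FALSE)
}

nexus_kv <- function(cmd, key) {
  pat <- paste0("(?i)\\b", key, "\\s*=\\s*(\"[^\"]*\"|'[^']*'|\\S+)")
  m <- regmatches(cmd, regexpr(pat, cmd, perl = TRUE))
  if (!length(m)) return(NA_character_)
  val <- sub(paste0("(?i)^", key, "\\s*=\\s*"), "", m, perl = TRUE)
  gsub("^['\"]|['\"]$", "", val)
}

parse_nexus_range <- function(s, nchar_) {
  idx <- integer(0)
  for (part in strsplit(trimws(s), "\\s+")[[1]]) {
    if (grepl("-", part)) {
      ab <- strsplit(part, "-")[[1]]
      hi <- if (ab[2] == ".") nchar_ else as.integer(ab[2])
      idx <- c(idx, seq(as.integer(ab[1]), hi))
    } else idx <- c(idx, as.integer(part))
  }
  if (any(is.na(idx)) || any(idx < 1) || any(idx > nchar_))
    stop("bad character range: ", s)
  idx
}

#' Write a character matrix to a NEXUS file
#'
#' Emits a DATA block (symbols, `missing=?`, `gap=-`) and a SETS block with
#' one `charset` per partition and `taxset`s for fossil and outgroup taxa.
#' Polymorphic cells are serialized as parenthesized digit runs.  The output
#' round-trips through [read_nexus_matrix()].
#'
#' @param matrix a [char_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(matrix, path) {
  validate_char_matrix(matrix)
  cells <- matrix$raw
  ser <- function(i) {
    row <- cells[i, ]
    poly <- nchar(row) > 1 & row != "?"
    row[poly] <- paste0("(", row[poly], ")")
    paste(row, collapse = "")
  }
  labs <- gsub("\\s", "_", matrix$taxa)
  width <- max(nchar(labs)) + 2
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(matrix$taxa),
            matrix$n_characters),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
    "  MATRIX"
  )
  for (i in seq_along(matrix$taxa))
    lines <- c(lines, sprintf("    %-*s%s", width, labs[i], ser(i)))
  lines <- c(lines, "  ;", "END;", "", "BEGIN SETS;")
  for (p in unique(matrix$partition)) {
    idx <- which(matrix$partition == p)
    lines <- c(lines, sprintf("  CHARSET %s = %s;", p, compress_ranges(idx)))
  }
  for (cls in c("fossil", "outgroup")) {
    members <- names(matrix$taxon_class)[matrix$taxon_class == cls]
    if (length(members))
      lines <- c(lines, sprintf("  TAXSET %s = %s;", cls,
                                paste(gsub("\\s", "_", members), collapse = " ")))
  }
  lines <- c(lines, "END;")
  writeLines(lines, path)
  invisible(path)
}

compress_ranges <- function(idx) {
  idx <- sort(idx)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = " ")
}
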