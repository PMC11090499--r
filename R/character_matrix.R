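# Multistate morphological character matrices: container + NEXUS/TNT I/O.
#
# Cells are stored as strings: "0" observed state, "02" polymorphic state
# set (sorted symbols), "?" missing, "-" inapplicable. The three marker
# semantics are kept distinct throughout; only the parsimony engine later
# collapses '?' and '-' to a wildcard.

#' Construct a character matrix
#'
#' @param taxa Character vector of unique taxon names (row order).
#' @param cells Character matrix (`length(taxa)` rows) whose entries are a
#'   sorted string of state symbols (singleton = observed, several =
#'   polymorphism), `"?"` (missing) or `"-"` (inapplicable).
#' @param descriptions Optional character vector of free-text character
#'   descriptions (one per column).
#' @param symbols Character vector of allowed single-character state
#'   symbols, default `0:9`.
#' @return An object of class `character_matrix` with fields `taxa`,
#'   `cells` (taxa in rownames, characters `1..K` in colnames),
#'   `descriptions`, `symbols`.
#' @examples
#' character_matrix(c("A", "B"), rbind(c("0", "1", "?"), c("1", "-", "01")))
#' @export
character_matrix <- function(taxa, cells, descriptions = NULL,
                             symbols = as.character(0:9)) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop_arg("taxa must be unique")
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (nrow(cells) != length(taxa))
    stop_arg("cells must have one row per taxon")
  cells <- matrix(vapply(cells, normalize_cell, "", symbols = symbols),
                  nrow = nrow(cells),
                  dimnames = list(taxa, seq_len(ncol(cells))))
  if (is.null(descriptions))
    descriptions <- paste("character", seq_len(ncol(cells)))
  if (length(descriptions) != ncol(cells))
    stop_arg("need one description per character")
  structure(list(taxa = taxa, cells = cells,
                 descriptions = as.character(descriptions),
                 symbols = symbols),
            class = "character_matrix")
}

# canonical cell form: markers kept, state strings sorted and deduplicated
normalize_cell <- function(cell, symbols) {
  if (is.na(cell)) return("?")
  if (cell %in% c("?", "-")) return(cell)
  st <- strsplit(cell, "", fixed = TRUE)[[1L]]
  bad <- setdiff(st, symbols)
  if (length(bad))
    stop_format("state symbol '%s' not in declared symbol list", bad[1L])
  if (!length(st)) stop_format("empty cell")
  paste(sort(unique(st)), collapse = "")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters\n",
              nrow(x$cells), ncol(x$cells)))
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

#' State set of one cell
#'
#' @param cm A [character_matrix()].
#' @param taxon Taxon name or row index.
#' @param character Character id (column index).
#' @return Integer vector of states, or `NA` for `'?'`/`'-'` markers.
#' @export
cell_states <- function(cm, taxon, character) {
  cell <- cm$cells[taxon, character]
  if (cell %in% c("?", "-")) return(NA_integer_)
  as.integer(strsplit(cell, "", fixed = TRUE)[[1L]])
}

## ---------------------------------------------------------------------
## Parsing

# split a cell sequence string into cells, honouring (..) [..] {..} groups
split_cell_run <- function(run, line_no) {
  chars <- strsplit(run, "", fixed = TRUE)[[1L]]
  cells <- character(0)
  i <- 1L
  n <- length(chars)
  closers <- c("(" = ")", "[" = "]", "{" = "}")
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% names(closers)) {
      j <- i + 1L
      grp <- character(0)
      while (j <= n && chars[j] != closers[[ch]]) {
        if (chars[j] != " ") grp <- c(grp, chars[j])
        j <- j + 1L
      }
      if (j > n)
        stop_format("line %d: unclosed '%s' state group", line_no, ch)
      if (!length(grp))
        stop_format("line %d: empty state group", line_no)
      cells <- c(cells, paste(grp, collapse = ""))
      i <- j + 1L
    } else {
      cells <- c(cells, ch)
      i <- i + 1L
    }
  }
  cells
}

# parse "name cells..." rows of a matrix body shared by both dialects
parse_matrix_rows <- function(lines, line_offset, ntax, nchar_, symbols) {
  taxa <- character(0)
  rows <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    line_no <- line_offset + k
    m <- regmatches(ln, regexec("^('[^']*'|\"[^\"]*\"|\\S+)\\s+(.*)$", ln))[[1L]]
    if (length(m) < 3L)
      stop_format("line %d: expected 'taxon cells' row", line_no)
    nm <- gsub("^['\"]|['\"]$", "", m[2L])
    cells <- split_cell_run(m[3L], line_no)
    if (nm %in% taxa) {
      # continuation row for an already-seen taxon (non-interleaved only)
      stop_format("line %d: duplicate taxon '%s'", line_no, nm)
    }
    for (cell in cells) {
      if (cell %in% c("?", "-")) next
      st <- strsplit(cell, "", fixed = TRUE)[[1L]]
      bad <- setdiff(st, symbols)
      if (length(bad))
        stop_format("line %d: undeclared symbol '%s'", line_no, bad[1L])
    }
    if (length(cells) != nchar_)
      stop_format("line %d: taxon '%s' has %d cells, expected %d",
                  line_no, nm, length(cells), nchar_)
    taxa <- c(taxa, nm)
    rows[[nm]] <- cells
  }
  if (length(taxa) != ntax)
    stop_format("matrix has %d taxa, declared NTAX=%d", length(taxa), ntax)
  do.call(rbind, rows)
}

#' Read a character matrix from NEXUS or TNT text
#'
#' Supports a NEXUS `CHARACTERS`/`DATA` block (non-interleaved, `STANDARD`
#' data) and the TNT `xread` dialect. Polymorphic cells may be written with
#' `(..)`, `[..]` or `{..}` in either dialect. Missing `'?'` and
#' inapplicable `'-'` markers are preserved as distinct.
#'
#' @param text Matrix text (string or vector of lines).
#' @param dialect `"nexus"` or `"tnt"`.
#' @param file Optional file path read instead of `text`.
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(text, dialect = c("nexus", "tnt"),
                                  file = NULL) {
  dialect <- match.arg(dialect)
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (dialect == "nexus") read_nexus_matrix(text) else read_tnt_matrix(text)
}

read_nexus_matrix <- function(lines) {
  up <- toupper(lines)
  beg <- grep("^\\s*BEGIN\\s+(CHARACTERS|DATA)\\s*;", up)
  if (!length(beg))
    stop_format("no CHARACTERS or DATA block found")
  beg <- beg[1L]
  end <- grep("^\\s*END\\s*;", up)
  end <- end[end > beg]
  if (!length(end)) stop_format("line %d: block not terminated by END;", beg)
  end <- end[1L]
  block <- lines[(beg + 1L):(end - 1L)]
  blocku <- toupper(block)

  dimln <- grep("DIMENSIONS", blocku)
  if (!length(dimln)) stop_format("DIMENSIONS statement missing")
  dl <- blocku[dimln[1L]]
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dl))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dl))
  if (is.na(ntax) || is.na(nchar_))
    stop_format("line %d: DIMENSIONS must give NTAX and NCHAR", beg + dimln[1L])

  symbols <- as.character(0:9)
  fmtln <- grep("FORMAT", blocku)
  if (length(fmtln)) {
    fl <- block[fmtln[1L]]
    sm <- regmatches(fl, regexec("[Ss][Yy][Mm][Bb][Oo][Ll][Ss]\\s*=\\s*\"([^\"]*)\"", fl))[[1L]]
    if (length(sm) == 2L)
      symbols <- setdiff(strsplit(sm[2L], "", fixed = TRUE)[[1L]], " ")
  }

  matln <- grep("^\\s*MATRIX\\s*$", blocku)
  if (!length(matln)) stop_format("MATRIX statement missing")
  matln <- matln[1L]
  body <- block[(matln + 1L):length(block)]
  term <- grep("^\\s*;\\s*$", body)
  if (!length(term))
    stop_format("line %d: MATRIX not terminated by ';'", beg + matln)
  body <- if (term[1L] > 1L) body[seq_len(term[1L] - 1L)] else character(0)
  cells <- parse_matrix_rows(body, beg + matln, ntax, nchar_, symbols)
  character_matrix(rownames(cells), cells, symbols = symbols)
}

read_tnt_matrix <- function(lines) {
  joined <- paste(lines, collapse = "\n")
  xr <- regexpr("(?i)xread", joined)
  if (xr < 0) stop_format("no xread statement found")
  rest <- substring(joined, xr + attr(xr, "match.length"))
  # optional quoted title
  rest <- sub("^\\s*'[^']*'", "", rest)
  dims <- regmatches(rest, regexec("^\\s*(\\d+)\\s+(\\d+)", rest))[[1L]]
  if (length(dims) < 3L)
    stop_format("xread must declare nchar and ntax")
  nchar_ <- as.integer(dims[2L])   # TNT order: nchar first, then ntax
  ntax <- as.integer(dims[3L])
  body <- sub("^\\s*\\d+\\s+\\d+", "", rest)
  semi <- regexpr(";", body, fixed = TRUE)
  if (semi < 0) stop_format("xread block not terminated by ';'")
  body <- substring(body, 1L, semi - 1L)
  body_lines <- strsplit(body, "\n", fixed = TRUE)[[1L]]
  xread_line <- length(strsplit(substring(joined, 1L, xr), "\n")[[1L]])
  cells <- parse_matrix_rows(body_lines, xread_line, ntax, nchar_,
                             symbols = as.character(0:9))
  character_matrix(rownames(cells), cells)
}

## ---------------------------------------------------------------------
## Writing

#' Write a character matrix as NEXUS or TNT text
#'
#' Output is deterministic (taxa and characters in stored order) and
#' round-trips through [read_character_matrix()] with identical cells.
#' Polymorphic cells are bracketed: `(..)` in NEXUS, `[..]` in TNT.
#'
#' @param cm A [character_matrix()].
#' @param dialect `"nexus"` or `"tnt"`.
#' @return A single string of matrix text.
#' @export
write_character_matrix <- function(cm, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (any(nchar(cm$symbols) != 1L) || length(cm$symbols) > 10L)
    stop_arg("unsupported alphabet: single-symbol dialects allow at most 10 one-character state symbols")
  open <- if (dialect == "tnt") "[" else "("
  close <- if (dialect == "tnt") "]" else ")"
  fmt_cell <- function(cell) {
    if (cell %in% c("?", "-") || nchar(cell) == 1L) cell
    else paste0(open, cell, close)
  }
  nm_w <- max(nchar(cm$taxa))
  rows <- vapply(seq_along(cm$taxa), function(i) {
    run <- paste(vapply(cm$cells[i, ], fmt_cell, ""), collapse = "")
    sprintf("%-*s %s", nm_w, cm$taxa[i], run)
  }, "")
  if (dialect == "nexus") {
    paste(c("#NEXUS",
            "BEGIN DATA;",
            sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                    nrow(cm$cells), ncol(cm$cells)),
            sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                    paste(cm$symbols, collapse = "")),
            "  MATRIX",
            paste0("    ", rows),
            "  ;",
            "END;", ""),
          collapse = "\n")
  } else {
    paste(c("xread",
            "'hetseq character matrix'",
            sprintf("%d %d", ncol(cm$cells), nrow(cm$cells)),
            rows,
            ";", ""),
          collapse = "\n")
  }
}
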