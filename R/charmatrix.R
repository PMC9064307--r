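# Discrete morphological character matrices.
#
# Cells are stored as a taxa x characters matrix of strings:
#   "2"     single state
#   "0/1"   polymorphic (set of states, "/"-separated, sorted)
#   NA      missing ('?')
#   ""      inapplicable ('-')
# State codes are non-negative integers 0..31, written with the symbol
# alphabet 0-9 then A-V.

.state_symbols <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUV", "")[[1]]

#' Construct a discrete character matrix
#'
#' @param cells character matrix (taxa x characters) of encoded cells: a
#'   single state code (`"1"`), a `"/"`-separated polymorphic set (`"0/1"`),
#'   `NA` for missing, `""` for inapplicable. Row names are taxon labels.
#' @param taxa taxon labels; defaults to `rownames(cells)`.
#' @param ordering per-character `"unordered"` or `"ordered"`, recycled.
#' @param weights per-character non-negative weights, recycled (default 1).
#' @return an object of class `character_matrix` with components `taxa`,
#'   `characters` (data frame: `index`, `ordering`, `weight`, list column
#'   `observed_states`) and `cells`.
#' @export
character_matrix <- function(cells, taxa = rownames(cells),
                             ordering = "unordered", weights = 1) {
  if (!is.matrix(cells) || !is.character(cells))
    stop("'cells' must be a character matrix")
  if (is.null(taxa)) stop("taxon labels required (rownames or 'taxa')")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(cells)) stop("length(taxa) != nrow(cells)")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  nc <- ncol(cells)
  ordering <- rep_len(as.character(ordering), nc)
  if (!all(ordering %in% c("unordered", "ordered")))
    stop("ordering must be 'unordered' or 'ordered'")
  weights <- rep_len(as.numeric(weights), nc)
  if (any(weights < 0) || anyNA(weights)) stop("weights must be >= 0")
  dimnames(cells) <- list(taxa, NULL)

  obs <- lapply(seq_len(nc), function(j) {
    sts <- sort(unique(unlist(lapply(cells[, j], decode_cell))))
    as.integer(sts)
  })
  for (j in seq_len(nc)) {
    st <- obs[[j]]
    if (length(st) && (any(st < 0) || any(st > 31)))
      stop("state codes must be in 0..31 (character ", j, ")")
  }
  m <- structure(
    list(taxa = taxa,
         characters = data.frame(index = seq_len(nc), ordering = ordering,
                                 weight = weights),
         cells = cells),
    class = "character_matrix")
  m$characters$observed_states <- obs
  m
}

# decode one encoded cell to an integer state vector (length 0 for
# missing/inapplicable)
decode_cell <- function(x) {
  if (is.na(x) || x == "") return(integer(0))
  as.integer(strsplit(x, "/", fixed = TRUE)[[1]])
}

# cell kind: "missing", "inapplicable", "single" or "polymorphic"
cell_kind <- function(x) {
  ifelse(is.na(x), "missing",
         ifelse(x == "", "inapplicable",
                ifelse(grepl("/", x, fixed = TRUE), "polymorphic", "single")))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Discrete character matrix: ", length(x$taxa), " taxa x ",
      nrow(x$characters), " characters\n", sep = "")
  cat("  ordered characters: ", sum(x$characters$ordering == "ordered"),
      "; mean completeness: ",
      round(mean(completeness(x)$taxon), 3), "\n", sep = "")
  invisible(x)
}

#' Number of taxa / characters
#' @param m a `character_matrix`.
#' @return integer count.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(m) nrow(m$characters)

#' Per-taxon and per-character completeness
#'
#' Fraction of cells carrying a score (single or polymorphic state), i.e.
#' neither missing nor inapplicable.
#'
#' @param m a `character_matrix`.
#' @return list with named numeric vectors `taxon` and `character`, each in
#'   \[0, 1\].
#' @export
completeness <- function(m) {
  scored <- !is.na(m$cells) & m$cells != ""
  list(taxon = rowMeans(scored), character = colMeans(scored))
}

#' Subset a character matrix
#'
#' Order-preserving subsetting by taxon label and/or character index.
#' Character indices are renumbered contiguously in the result.
#'
#' @param m a `character_matrix`.
#' @param taxa taxon labels to keep (default all).
#' @param characters character indices to keep (default all).
#' @return a `character_matrix`.
#' @export
subset_matrix <- function(m, taxa = NULL, characters = NULL) {
  if (is.null(taxa)) taxa <- m$taxa
  unknown <- setdiff(taxa, m$taxa)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (is.null(characters)) characters <- m$characters$index
  if (!all(characters %in% m$characters$index))
    stop("unknown character indices")
  keep_taxa <- m$taxa[m$taxa %in% taxa]  # preserve original row order
  if (length(keep_taxa) == 0L) stop("subset would remove all taxa")
  character_matrix(m$cells[keep_taxa, characters, drop = FALSE],
                   taxa = keep_taxa,
                   ordering = m$characters$ordering[characters],
                   weights = m$characters$weight[characters])
}

# ---- NEXUS I/O --------------------------------------------------------------

# strip [...] comments (non-nested is all we support) and collapse whitespace
strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", " ", txt)

#' Read a discrete character matrix from a NEXUS file
#'
#' Supports a non-interleaved CHARACTERS or DATA block with SYMBOLS, MISSING
#' and GAP declared in FORMAT; polymorphic cells written as `{01}` or `(01)`;
#' an optional ASSUMPTIONS block with a TYPESET (`ord`/`unord`) and WTSET.
#' The MISSING symbol maps to missing, the GAP symbol to inapplicable.
#'
#' @param path NEXUS file.
#' @param meta_csv optional sidecar CSV with columns `index,ordering,weight`
#'   overriding the in-file ordering/weight assumptions.
#' @return a `character_matrix`.
#' @export
read_nexus <- function(path, meta_csv = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- strip_nexus_comments(txt)

  dim_m <- regmatches(txt, regexpr("(?i)DIMENSIONS[^;]*;", txt, perl = TRUE))
  if (!length(dim_m)) stop("NEXUS parse error: no DIMENSIONS statement")
  ntax <- as.integer(sub(".*(?i)NTAX\\s*=\\s*(\\d+).*", "\\1", dim_m, perl = TRUE))
  nchar_ <- as.integer(sub(".*(?i)NCHAR\\s*=\\s*(\\d+).*", "\\1", dim_m, perl = TRUE))
  if (is.na(ntax) || is.na(nchar_)) stop("NEXUS parse error: bad DIMENSIONS")

  fmt <- regmatches(txt, regexpr("(?i)FORMAT[^;]*;", txt, perl = TRUE))
  missing_sym <- "?"; gap_sym <- "-"; symbols <- .state_symbols
  if (length(fmt)) {
    g <- function(p) {
      mm <- regmatches(fmt, regexpr(p, fmt, perl = TRUE))
      if (length(mm)) sub(p, "\\1", mm, perl = TRUE) else NULL
    }
    ms <- g("(?i)MISSING\\s*=\\s*(\\S)"); if (!is.null(ms)) missing_sym <- ms
    gs <- g("(?i)GAP\\s*=\\s*(\\S)"); if (!is.null(gs)) gap_sym <- gs
    sy <- g('(?i)SYMBOLS\\s*=\\s*"([^"]*)"')
    if (!is.null(sy)) symbols <- strsplit(gsub("\\s", "", sy), "")[[1]]
  }
  if (!all(symbols %in% .state_symbols))
    stop("unsupported SYMBOLS; allowed: ", paste(.state_symbols, collapse = ""))

  mat_m <- regmatches(txt, regexpr("(?si)MATRIX\\s.*?;", txt, perl = TRUE))
  if (!length(mat_m)) stop("NEXUS parse error: no MATRIX")
  body <- sub("(?i)^MATRIX", "", mat_m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[nzchar(rows)]

  taxa <- character(0); cell_rows <- list()
  for (r in rows) {
    if (startsWith(r, "'")) {
      cl <- regmatches(r, regexpr("^'[^']*'", r))
      taxon <- gsub("^'|'$", "", cl)
      rest <- trimws(substring(r, nchar(cl) + 1L))
    } else {
      sp <- regexpr("\\s", r)
      if (sp < 0) stop("NEXUS parse error: row without states: ", r)
      taxon <- substring(r, 1L, sp - 1L)
      rest <- trimws(substring(r, sp + 1L))
    }
    taxon <- gsub("_", " ", taxon)
    cells <- parse_state_string(gsub("\\s", "", rest), symbols,
                                missing_sym, gap_sym, taxon)
    if (length(cells) != nchar_)
      stop("ragged NEXUS matrix: taxon '", taxon, "' has ", length(cells),
           " characters, expected ", nchar_)
    taxa <- c(taxa, taxon)
    cell_rows[[length(cell_rows) + 1L]] <- cells
  }
  if (length(taxa) != ntax)
    stop("NEXUS parse error: found ", length(taxa), " taxa, NTAX=", ntax)
  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- taxa

  ordering <- rep("unordered", nchar_); weights <- rep(1, nchar_)
  ts <- regmatches(txt, regexpr("(?i)TYPESET[^;]*;", txt, perl = TRUE))
  if (length(ts)) {
    spec <- sub(".*?=", "", sub(";$", "", ts))
    for (part in strsplit(spec, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(part, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2) next
      type <- trimws(tolower(kv[1]))
      idx <- parse_index_list(kv[2], nchar_)
      if (type %in% c("ord", "ordered")) ordering[idx] <- "ordered"
    }
  }
  ws <- regmatches(txt, regexpr("(?i)WTSET[^;]*;", txt, perl = TRUE))
  if (length(ws)) {
    spec <- sub(".*?=", "", sub(";$", "", ws))
    for (part in strsplit(spec, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(part, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2) next
      w <- suppressWarnings(as.numeric(trimws(kv[1])))
      if (!is.na(w)) weights[parse_index_list(kv[2], nchar_)] <- w
    }
  }
  if (!is.null(meta_csv)) {
    meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
    stopifnot(all(c("index", "ordering", "weight") %in% names(meta)))
    ordering[meta$index] <- meta$ordering
    weights[meta$index] <- meta$weight
  }
  character_matrix(cells, ordering = ordering, weights = weights)
}

# parse a concatenated state string ("01{01}?-") into encoded cells
parse_state_string <- function(s, symbols, missing_sym, gap_sym, taxon) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L; set <- integer(0)
      while (j <= n && chars[j] != close) {
        set <- c(set, symbol_to_state(chars[j], symbols, taxon, length(out) + 1L))
        j <- j + 1L
      }
      if (j > n) stop("unclosed polymorphism in taxon '", taxon, "'")
      if (length(set) < 1) stop("empty polymorphism in taxon '", taxon, "'")
      out <- c(out, paste(sort(unique(set)), collapse = "/"))
      i <- j + 1L
    } else if (ch == missing_sym) {
      out <- c(out, NA_character_); i <- i + 1L
    } else if (ch == gap_sym) {
      out <- c(out, ""); i <- i + 1L
    } else {
      out <- c(out, as.character(symbol_to_state(ch, symbols, taxon,
                                                 length(out) + 1L)))
      i <- i + 1L
    }
  }
  out
}

symbol_to_state <- function(ch, symbols, taxon, char_index) {
  if (!(ch %in% symbols))
    stop("undeclared symbol '", ch, "' at character ", char_index,
         " of taxon '", taxon, "'")
  match(ch, .state_symbols) - 1L
}

# "1 3-5" -> c(1,3,4,5)
parse_index_list <- function(s, nmax) {
  out <- integer(0)
  for (tok in strsplit(trimws(s), "\\s+")[[1]]) {
    if (grepl("-", tok, fixed = TRUE)) {
      ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(tok))
  }
  out <- out[out >= 1 & out <= nmax]
  out
}

#' Write a character matrix as NEXUS
#'
#' Inverse of [read_nexus()] on the supported dialect; ordering is written to
#' an ASSUMPTIONS TYPESET and non-unit weights to a WTSET.
#'
#' @param m a `character_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path) {
  if (length(m$taxa) == 0L) stop("cannot write a matrix with no taxa")
  max_state <- suppressWarnings(max(unlist(m$characters$observed_states), -1L))
  if (max_state > 31) stop("state code ", max_state, " beyond SYMBOLS range")
  symbols <- .state_symbols[seq_len(max(max_state + 1L, 2L))]

  enc_row <- function(i) {
    paste(vapply(m$cells[i, ], function(x) {
      st <- decode_cell(x)
      if (is.na(x)) "?"
      else if (x == "") "-"
      else if (length(st) == 1L) .state_symbols[st + 1L]
      else paste0("{", paste(.state_symbols[st + 1L], collapse = ""), "}")
    }, character(1)), collapse = "")
  }
  labels <- gsub(" ", "_", m$taxa)
  pad <- max(nchar(labels)) + 2L
  lines <- c(
    "#NEXUS", "",
    "BEGIN DATA;",
    sprintf("\tDIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa),
            nrow(m$characters)),
    sprintf("\tFORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(symbols, collapse = "")),
    "\tMATRIX",
    vapply(seq_along(m$taxa), function(i)
      sprintf("%-*s%s", pad, labels[i], enc_row(i)), character(1)),
    "\t;", "END;")

  ord_idx <- which(m$characters$ordering == "ordered")
  unord_idx <- which(m$characters$ordering == "unordered")
  parts <- character(0)
  if (length(ord_idx))
    parts <- c(parts, paste0("ord: ", paste(ord_idx, collapse = " ")))
  if (length(unord_idx))
    parts <- c(parts, paste0("unord: ", paste(unord_idx, collapse = " ")))
  assume <- c("", "BEGIN ASSUMPTIONS;",
              sprintf("\tTYPESET * default = %s;", paste(parts, collapse = ", ")))
  w <- m$characters$weight
  if (any(w != 1)) {
    wparts <- vapply(split(seq_along(w), w), function(idx)
      paste0(w[idx[1]], ": ", paste(idx, collapse = " ")), character(1))
    assume <- c(assume, sprintf("\tWTSET * default = %s;",
                                paste(wparts, collapse = ", ")))
  }
  assume <- c(assume, "END;")
  writeLines(c(lines, assume), path)
  invisible(path)
}
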