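## Sequence / MSA data model and FASTA / a3m readers and writers.
##
## Two alignment dialects are supported:
##   ALIGNED_FASTA - all rows equal length, characters = residues or '-'
##   A3M           - uppercase/'-' are match states, lowercase letters are
##                   insertions relative to the query; the number of match
##                   states is identical across rows
## An optional '#' header line on a3m files declares per-component query
## lengths and cardinalities for complex prediction ("#L1,L2\t1,1").

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Amino-acid sequence record
#'
#' A minimal sequence container: an identifier (no whitespace), an optional
#' free-text description, and an uppercase residue string over the 20
#' standard amino acids plus `X`. Barcoded sequences (see [barcode()])
#' additionally allow the placeholder letters used to tag anchor cysteines.
#'
#' @param id Identifier, unique within a collection; must not contain
#'   whitespace.
#' @param residues Uppercase residue string, no gaps.
#' @param description Optional description (the remainder of a FASTA header).
#' @param alphabet `"aa"` (default) or `"barcoded"` (placeholders allowed).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", alphabet = c("aa", "barcoded")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, is.character(residues), length(residues) == 1L)
  if (grepl("[[:space:]]", id) || !nzchar(id)) {
    stop("sequence id must be non-empty and contain no whitespace: ", sQuote(id))
  }
  if (!nzchar(residues)) stop("empty sequence record: ", sQuote(id))
  allowed <- if (alphabet == "aa") AA_LETTERS else c(AA_LETTERS, cys_placeholders_chars())
  bad <- which(!(strsplit(residues, "")[[1]] %in% allowed))
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue character in sequence '%s' at position %d: '%s'",
                 id, bad[1L], substr(residues, bad[1L], bad[1L])))
  }
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Multiple sequence alignment container
#'
#' @param ids Character vector of row identifiers (parallel to `rows`).
#' @param rows Character vector of row strings.
#' @param dialect `"ALIGNED_FASTA"` or `"A3M"`.
#' @param validate Check dialect invariants (default `TRUE`).
#' @return An object of class `msa` with fields `ids`, `rows`, `dialect`.
#' @export
msa <- function(ids, rows, dialect = c("ALIGNED_FASTA", "A3M"), validate = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(ids), is.character(rows), length(ids) == length(rows))
  if (length(rows) == 0L) stop("an msa must contain at least one row")
  obj <- structure(list(ids = ids, rows = rows, dialect = dialect), class = "msa")
  if (validate) validate_msa(obj)
  obj
}

validate_msa <- function(x) {
  if (x$dialect == "ALIGNED_FASTA") {
    if (length(unique(nchar(x$rows))) != 1L) {
      stop("ALIGNED_FASTA rows must all have equal length")
    }
    if (any(grepl("[^A-Z0-9-]", x$rows))) {
      stop("ALIGNED_FASTA rows may only contain uppercase residues and '-'")
    }
  } else {
    if (any(grepl("[^A-Za-z0-9-]", x$rows))) {
      stop("A3M rows may only contain letters, digits and '-'")
    }
    counts <- vapply(x$rows, n_match_states, integer(1), USE.NAMES = FALSE)
    if (length(unique(counts)) != 1L) {
      stop("inconsistent match-state counts across a3m rows: ",
           paste(unique(counts), collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows, dialect %s, width %d\n",
              length(x$rows), x$dialect,
              if (x$dialect == "A3M") n_match_states(x$rows[1L]) else nchar(x$rows[1L])))
  invisible(x)
}

# number of match states (uppercase, digits, '-') in an a3m row
n_match_states <- function(row) {
  nchar(gsub("[a-z]", "", row))
}

# match-state string of an a3m row (insertions removed)
match_states <- function(row) {
  gsub("[a-z]", "", row)
}

# remove gaps and uppercase: recovers the underlying residues of a row
ungap <- function(row) {
  toupper(gsub("-", "", row, fixed = TRUE))
}

#' Pairing header of a complex a3m file
#'
#' The first line of a complex-prediction a3m file declares the query length
#' and copy number of each component, e.g. `#352,75<TAB>1,1` for a
#' receptor-ligand heterodimer.
#'
#' @param lengths Positive integer vector of per-component query lengths.
#' @param cardinalities Positive integer vector of copies per component.
#' @return An object of class `pairing_header`.
#' @export
pairing_header <- function(lengths, cardinalities = rep(1L, length(lengths))) {
  lengths <- as.integer(lengths)
  cardinalities <- as.integer(cardinalities)
  if (length(lengths) < 1L || length(lengths) != length(cardinalities)) {
    stop("lengths and cardinalities must have equal count >= 1")
  }
  if (any(lengths < 1L) || any(cardinalities < 1L)) {
    stop("pairing header entries must be positive")
  }
  structure(list(lengths = lengths, cardinalities = cardinalities),
            class = "pairing_header")
}

format_pairing_header <- function(h) {
  paste0("#", paste(h$lengths, collapse = ","), "\t",
         paste(h$cardinalities, collapse = ","))
}

parse_pairing_header <- function(line) {
  body <- sub("^#", "", line)
  parts <- strsplit(body, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed pairing header: ", sQuote(line))
  lens <- suppressWarnings(as.integer(strsplit(parts[1L], ",", fixed = TRUE)[[1]]))
  card <- suppressWarnings(as.integer(strsplit(parts[2L], ",", fixed = TRUE)[[1]]))
  if (anyNA(lens) || anyNA(card)) stop("malformed pairing header: ", sQuote(line))
  pairing_header(lens, card)
}

read_lines_any <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  stopifnot(is.character(source))
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  # literal text: one string with newlines, or already-split lines
  if (length(source) == 1L) strsplit(source, "\n", fixed = TRUE)[[1]] else source
}

# split FASTA-like lines into records; returns list(ids, descs, seqs)
parse_fasta_records <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no FASTA records found")
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("FASTA input must start with a '>' header line")
  rec <- cumsum(hdr)
  ids <- character(sum(hdr)); descs <- character(sum(hdr)); seqs <- character(sum(hdr))
  for (k in seq_len(sum(hdr))) {
    block <- lines[rec == k]
    header <- sub("^>", "", block[1L])
    tok <- strsplit(trimws(header), "[[:space:]]+")[[1]]
    ids[k] <- if (length(tok) >= 1L) tok[1L] else ""
    descs[k] <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ") else ""
    seqs[k] <- paste(gsub("[[:space:]]", "", block[-1L]), collapse = "")
    if (!nzchar(ids[k])) stop("FASTA record ", k, " has an empty id")
    if (!nzchar(seqs[k])) stop("empty FASTA record: ", sQuote(ids[k]))
  }
  list(ids = ids, descs = descs, seqs = seqs)
}

#' Read amino-acid sequences from FASTA
#'
#' Sequence lines may wrap; the id is the first whitespace-delimited token of
#' the header. Duplicate ids and residues outside the amino-acid alphabet
#' (20 letters plus `X`) are rejected with the offending id and position.
#'
#' @param source File path, connection, or literal FASTA text.
#' @param alphabet Passed to [seq_record()]; use `"barcoded"` to accept
#'   placeholder letters.
#' @return List of [seq_record()] objects, input order preserved.
#' @export
read_fasta <- function(source, alphabet = "aa") {
  rec <- parse_fasta_records(read_lines_any(source))
  if (anyDuplicated(rec$ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(rec$ids[duplicated(rec$ids)]), collapse = ", "))
  }
  mapply(function(i, d, s) seq_record(i, toupper(s), d, alphabet = alphabet),
         rec$ids, rec$descs, rec$seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' Each sequence is written on a single line so fixture diffs are byte exact.
#'
#' @param seqs List of [seq_record()] objects.
#' @param path Output file path, or `NULL` to return the text.
#' @export
write_fasta <- function(seqs, path = NULL) {
  lines <- unlist(lapply(seqs, function(s) {
    hdr <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    c(paste0(">", hdr), s$residues)
  }))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read an alignment in aligned-FASTA dialect
#'
#' @param source File path, connection, or literal text.
#' @return An [msa()] with dialect `ALIGNED_FASTA`.
#' @export
read_aligned_fasta <- function(source) {
  rec <- parse_fasta_records(read_lines_any(source))
  if (anyDuplicated(rec$ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(rec$ids[duplicated(rec$ids)]), collapse = ", "))
  }
  msa(rec$ids, toupper(rec$seqs), dialect = "ALIGNED_FASTA")
}

#' Write an aligned-FASTA alignment
#'
#' @param x An [msa()] with dialect `ALIGNED_FASTA`.
#' @param path Output path or `NULL` for text.
#' @export
write_aligned_fasta <- function(x, path = NULL) {
  stopifnot(inherits(x, "msa"))
  if (x$dialect != "ALIGNED_FASTA") stop("msa dialect must be ALIGNED_FASTA")
  lines <- as.vector(rbind(paste0(">", x$ids), x$rows))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read an a3m alignment
#'
#' Accepts the complex-prediction dialect: an optional first line starting
#' with `#` declaring per-component query lengths and cardinalities
#' (`#L1,L2<TAB>1,1`). Lowercase letters are insertion states; uppercase and
#' `-` are match states. All rows must agree on the match-state count, and
#' when the header is present that count must equal the sum of the declared
#' lengths.
#'
#' @param source File path, connection, or literal text.
#' @param strict_ids Reject duplicate row ids (default `TRUE`). Complex
#'   bundles legitimately repeat the query id across blocks; the bundle
#'   reader passes `FALSE`.
#' @return `list(msa =` [msa()] with dialect `A3M`, `header =`
#'   [pairing_header()] or `NULL)`.
#' @export
read_a3m <- function(source, strict_ids = TRUE) {
  lines <- read_lines_any(source)
  header <- NULL
  if (length(lines) > 0L && grepl("^#", lines[1L])) {
    header <- parse_pairing_header(lines[1L])
    lines <- lines[-1L]
  }
  rec <- parse_fasta_records(lines)
  if (strict_ids && anyDuplicated(rec$ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(rec$ids[duplicated(rec$ids)]), collapse = ", "))
  }
  m <- msa(rec$ids, rec$seqs, dialect = "A3M")
  if (!is.null(header)) {
    want <- sum(header$lengths * header$cardinalities)
    got <- n_match_states(m$rows[1L])
    if (got != want) {
      stop(sprintf("match-state count (%d) does not equal the header total (%d)",
                   got, want))
    }
  }
  list(msa = m, header = header)
}

#' Write an a3m alignment
#'
#' Byte-exact round trip with [read_a3m()]: single-line sequences, `\n`
#' newlines, and the pairing header (when given) emitted as the first line.
#'
#' @param x An [msa()] with dialect `A3M`.
#' @param header Optional [pairing_header()].
#' @param path Output path or `NULL` for text.
#' @export
write_a3m <- function(x, header = NULL, path = NULL) {
  stopifnot(inherits(x, "msa"))
  if (x$dialect != "A3M") stop("msa dialect must be A3M")
  lines <- as.vector(rbind(paste0(">", x$ids), x$rows))
  if (!is.null(header)) {
    stopifnot(inherits(header, "pairing_header"))
    lines <- c(format_pairing_header(header), lines)
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

# per-row decomposition of an a3m row: match characters and the insertion
# string attached after each match column (slot 0 = leading insertion)
a3m_decompose <- function(row) {
  chars <- strsplit(row, "")[[1]]
  is_ins <- grepl("[a-z]", chars)
  m <- sum(!is_ins)
  ins <- character(m + 1L)
  match_chars <- character(m)
  slot <- 0L
  for (ch in chars) {
    if (grepl("[a-z]", ch)) {
      ins[slot + 1L] <- paste0(ins[slot + 1L], ch)
    } else {
      slot <- slot + 1L
      match_chars[slot] <- ch
    }
  }
  list(match = match_chars, ins = ins)
}

#' Expand an a3m alignment to aligned FASTA
#'
#' Every insertion becomes explicit gap columns in all other rows. Insertions
#' sharing a slot are left-justified within the expanded block. Row residues
#' are conserved (ungapped/uppercased rows are unchanged).
#'
#' @param x An [msa()] with dialect `A3M`.
#' @return An [msa()] with dialect `ALIGNED_FASTA`.
#' @export
a3m_to_aligned <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (x$dialect != "A3M") stop("msa dialect must be A3M")
  dec <- lapply(x$rows, a3m_decompose)
  m <- length(dec[[1L]]$match)
  ins_len <- integer(m + 1L)
  for (d in dec) ins_len <- pmax(ins_len, nchar(d$ins))
  rows <- vapply(dec, function(d) {
    pieces <- character(0)
    for (slot in 0:m) {
      block <- toupper(d$ins[slot + 1L])
      pad <- ins_len[slot + 1L] - nchar(block)
      pieces <- c(pieces, paste0(block, strrep("-", pad)))
      if (slot < m) pieces <- c(pieces, d$match[slot + 1L])
    }
    paste(pieces, collapse = "")
  }, character(1))
  msa(x$ids, rows, dialect = "ALIGNED_FASTA")
}

#' Convert aligned FASTA to a3m relative to a reference row
#'
#' Columns where the reference row carries a gap become lowercase insertions
#' in the other rows (gaps there are dropped) and are deleted from the
#' reference; the reference row is moved to the top.
#'
#' @param x An [msa()] with dialect `ALIGNED_FASTA`.
#' @param reference_id Row to use as the (gap-free) a3m query.
#' @return An [msa()] with dialect `A3M`, reference first.
#' @export
aligned_to_a3m <- function(x, reference_id) {
  stopifnot(inherits(x, "msa"))
  if (x$dialect != "ALIGNED_FASTA") stop("msa dialect must be ALIGNED_FASTA")
  ref <- match(reference_id, x$ids)
  if (is.na(ref)) stop("unknown reference id: ", sQuote(reference_id))
  ref_chars <- strsplit(x$rows[ref], "")[[1]]
  is_match_col <- ref_chars != "-"
  rows <- vapply(x$rows, function(r) {
    chars <- strsplit(r, "")[[1]]
    out <- ifelse(is_match_col, chars, ifelse(chars == "-", "", tolower(chars)))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ord <- c(ref, setdiff(seq_along(x$ids), ref))
  msa(x$ids[ord], rows[ord], dialect = "A3M")
}

#' Move a row to the top of an alignment
#'
#' The designated row becomes the query (first row); the relative order of
#' all other rows is preserved.
#'
#' @param x An [msa()].
#' @param id Row id to promote.
#' @return The reordered [msa()].
#' @export
promote_query <- function(x, id) {
  stopifnot(inherits(x, "msa"))
  i <- match(id, x$ids)
  if (is.na(i)) stop("unknown id: ", sQuote(id))
  ord <- c(i, setdiff(seq_along(x$ids), i))
  msa(x$ids[ord], x$rows[ord], dialect = x$dialect, validate = FALSE)
}
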