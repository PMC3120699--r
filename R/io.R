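#' Read a multi-record FASTA file of RNA sequences
#'
#' Residues are normalized on input: lower case is folded to upper case and
#' T (DNA notation) is mapped to U. Records whose residues fall outside
#' A, C, G, U, T trigger an error naming the record and the offending
#' position; the ambiguity code N is rejected rather than treated as
#' unpairable. Duplicate record identifiers are disambiguated
#' deterministically by suffixing `_2`, `_3`, ... in file order.
#'
#' @param path Path to a FASTA file.
#' @return List of [rna_sequence] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1L] != 1L) {
    stop(sprintf("not FASTA-formatted (no leading '>' record): %s", path), call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- sub("^>\\s*", "", lines[starts])
  ids <- sub("\\s.*$", "", ids)        # id = first whitespace-delimited token
  seen <- character(0)
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    id <- ids[r]
    if (!nzchar(id)) id <- sprintf("seq_%d", r)
    if (id %in% seen) {
      k <- 2L
      while (sprintf("%s_%d", id, k) %in% seen) k <- k + 1L
      id <- sprintf("%s_%d", id, k)
    }
    seen <- c(seen, id)
    body <- if (ends[r] >= starts[r] + 1L) lines[(starts[r] + 1L):ends[r]] else character(0)
    res <- strsplit(gsub("\\s", "", paste(body, collapse = "")), "", fixed = TRUE)[[1L]]
    if (length(res) == 0L) {
      stop(sprintf("FASTA record '%s' has no residues", id), call. = FALSE)
    }
    resu <- toupper(res)
    bad <- which(!resu %in% c("A", "C", "G", "U", "T"))
    if (length(bad) > 0L) {
      stop(sprintf("FASTA record '%s': invalid residue '%s' at position %d",
                   id, res[bad[1L]], bad[1L]), call. = FALSE)
    }
    out[[r]] <- rna_sequence(id, resu)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A list of [rna_sequence] objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    txt <- paste(s$residues, collapse = "")
    starts <- seq(1L, nchar(txt), by = width)
    writeLines(substring(txt, starts, pmin(starts + width - 1L, nchar(txt))), con)
  }
  invisible(path)
}

#' Read a CT (connectivity table) structure file
#'
#' Standard six-column CT as used throughout the RNA structure software
#' ecosystem: index, base, index-1, index+1, pairing partner (0 =
#' unpaired), index. The pairing column must be symmetric: if row i names
#' partner j, row j must name partner i.
#'
#' @param path Path to a CT file.
#' @return List with elements `seq` ([rna_sequence]) and `structure`
#'   ([secondary_structure]).
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 1L) stop(sprintf("empty CT file: %s", path), call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(n) || n < 1L) stop(sprintf("bad CT header in %s", path), call. = FALSE)
  title <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else "structure"
  if (length(lines) < n + 1L) stop(sprintf("CT file %s truncated: expected %d rows", path, n), call. = FALSE)
  rows <- lapply(lines[2L:(n + 1L)], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  base <- vapply(rows, `[`, character(1L), 2L)
  partner <- vapply(rows, function(r) suppressWarnings(as.integer(r[5L])), integer(1L))
  if (anyNA(partner)) stop(sprintf("CT file %s: non-integer pairing column", path), call. = FALSE)
  if (any(partner < 0L | partner > n)) {
    bad <- which(partner < 0L | partner > n)[1L]
    stop(sprintf("CT file %s: partner index %d out of range at row %d",
                 path, partner[bad], bad), call. = FALSE)
  }
  paired <- which(partner > 0L)
  if (any(partner[partner[paired]] != paired)) {
    bad <- paired[which(partner[partner[paired]] != paired)[1L]]
    stop(sprintf("CT file %s: asymmetric pair at row %d (partner %d does not point back)",
                 path, bad, partner[bad]), call. = FALSE)
  }
  if (any(partner[paired] == paired)) stop(sprintf("CT file %s: self-pairing row", path), call. = FALSE)
  up <- paired[partner[paired] > paired]
  pairs <- cbind(up, partner[up])
  list(seq = rna_sequence(title, base),
       structure = secondary_structure(pairs, n))
}

#' Write a CT structure file
#'
#' Validity of the structure (including pairing-column symmetry, which is
#' implied by the internal pair representation) is checked before writing.
#'
#' @param seq An [rna_sequence].
#' @param structure A [secondary_structure] on the same length.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ct <- function(seq, structure, path) {
  if (structure$length != seq$length) {
    stop("structure length does not match sequence length", call. = FALSE)
  }
  ok <- is_valid_structure(structure)
  if (!isTRUE(ok)) stop(sprintf("refusing to write invalid structure: %s", attr(ok, "why")), call. = FALSE)
  n <- seq$length
  v <- partner_vector(structure)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, seq$id), con)
  writeLines(sprintf("%d %s %d %d %d %d",
                     seq_len(n), seq$residues, seq_len(n) - 1L,
                     c(seq_len(n - 1L) + 1L, 0L), v, seq_len(n)), con)
  invisible(path)
}

#' Parse a dot-bracket string
#'
#' Vienna dialect over `.`, `(` and `)`; no pseudoknot bracket alphabets.
#' Unbalanced brackets raise an error reporting the offending position.
#'
#' @param text Dot-bracket string.
#' @return A [secondary_structure] of length `nchar(text)`.
#' @export
parse_dotbracket <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid dot-bracket character '%s' at position %d", chars[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop(sprintf("unbalanced '(' at position %d", stack[length(stack)]), call. = FALSE)
  }
  secondary_structure(pairs, length(chars))
}

#' Write a structure as a dot-bracket string
#'
#' Only valid for pseudoknot-free structures; validity is checked first.
#'
#' @param structure A [secondary_structure].
#' @return Dot-bracket string of length `structure$length`.
#' @export
write_dotbracket <- function(structure) {
  ok <- is_valid_structure(structure)
  if (!isTRUE(ok)) stop(sprintf("cannot write pseudoknotted/invalid structure: %s", attr(ok, "why")), call. = FALSE)
  chars <- rep(".", structure$length)
  if (nrow(structure$pairs) > 0L) {
    chars[structure$pairs[, 1L]] <- "("
    chars[structure$pairs[, 2L]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Write a base-pair probability matrix as tab-separated triples
#'
#' Text format: header line `# seq_id N`, then rows `i<TAB>j<TAB>p` with
#' 1-based i < j. Only entries above `floor` are written (default 1e-6,
#' well below any thresholding- or MEA-relevant magnitude), with 12+
#' significant digits so a round trip is faithful to the stored values.
#'
#' @param m Symmetric N x N probability matrix (see [modified_partition]).
#' @param path Output path.
#' @param seq_id Identifier written in the header.
#' @param floor Smallest probability that is written out.
#' @return Invisibly, `path`.
#' @export
write_bpp <- function(m, path, seq_id = "seq", floor = 1e-6) {
  n <- nrow(m)
  if (is.null(n) || n != ncol(m)) stop("probability matrix must be square", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %d", seq_id, n), con)
  idx <- which(upper.tri(m) & m > floor, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%.14g", idx[, 1L], idx[, 2L], m[idx]), con)
  }
  invisible(path)
}

#' Read a base-pair probability matrix written by [write_bpp]
#'
#' @param path Path to a BPP text file.
#' @param n Sequence length; defaults to the value recorded in the header.
#' @return Symmetric `n x n` numeric matrix with attribute `seq_id`.
#' @export
read_bpp <- function(path, n = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#", lines[1L])) {
    stop(sprintf("BPP file %s missing '# seq_id N' header", path), call. = FALSE)
  }
  hdr <- strsplit(trimws(sub("^#\\s*", "", lines[1L])), "\\s+")[[1L]]
  n_hdr <- suppressWarnings(as.integer(hdr[length(hdr)]))
  if (is.null(n)) n <- n_hdr
  if (is.na(n) || n < 1L) stop(sprintf("BPP file %s: bad length in header", path), call. = FALSE)
  m <- matrix(0, n, n)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  for (line in body) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    i <- as.integer(f[1L]); j <- as.integer(f[2L]); p <- as.numeric(f[3L])
    if (is.na(i) || is.na(j) || is.na(p)) stop(sprintf("BPP file %s: malformed row '%s'", path, line), call. = FALSE)
    if (i >= j) stop(sprintf("BPP file %s: row with i >= j (%d, %d)", path, i, j), call. = FALSE)
    if (j > n) stop(sprintf("BPP file %s: index %d exceeds length %d", path, j, n), call. = FALSE)
    if (p < 0 || p > 1) stop(sprintf("BPP file %s: probability %g outside [0,1]", path, p), call. = FALSE)
    m[i, j] <- p
    m[j, i] <- p
  }
  attr(m, "seq_id") <- paste(hdr[-length(hdr)], collapse = " ")
  m
}
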