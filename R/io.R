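#' Construct an evolutionary profile object
#'
#' A profile is the per-protein substrate of the profile kernel: an `L x 20`
#' matrix of non-negative per-position "conservation costs", one column per
#' residue in [aa_alphabet()] order. A low cost means the residue is well
#' tolerated (conserved) at that position; the kernel sums costs over a
#' k-mer and keeps it when the sum falls below the threshold sigma.
#'
#' @param id Protein identifier (non-empty string).
#' @param scores `L x 20` numeric matrix of finite, non-negative costs.
#' @param source `"pssm-derived"` or `"synthetic"`.
#' @param sequence Optional amino-acid sequence of length `L`.
#' @return An object of class `snl_profile`.
#' @export
new_profile <- function(id, scores, source = c("pssm-derived", "synthetic"),
                        sequence = NULL) {
  source <- match.arg(source)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("profile id must be a non-empty string")
  }
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop("profile score matrix must have 20 columns, got ", ncol(scores))
  }
  if (nrow(scores) < 1L) stop("profile must have at least one position")
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop("profile scores must be finite and non-negative")
  }
  if (!is.null(sequence) && nchar(sequence) != nrow(scores)) {
    stop("sequence length (", nchar(sequence),
         ") does not match profile length (", nrow(scores), ")")
  }
  colnames(scores) <- aa_alphabet()
  structure(list(id = id, scores = scores, source = source,
                 sequence = sequence),
            class = "snl_profile")
}

#' @export
print.snl_profile <- function(x, ...) {
  cat("<snl_profile> ", x$id, ": ", nrow(x$scores), " positions (",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Length of a profile in positions
#' @param profile An `snl_profile`.
#' @return Integer number of positions.
#' @export
profile_length <- function(profile) nrow(profile$scores)

#' Build an annotation database
#'
#' Holds the observed localization of each protein: a non-empty set of
#' compartment labels from the 13-label vocabulary, and an optional
#' "traveler" flag marking proteins also functional outside the nucleus.
#'
#' @param labels Named list: protein id -> character vector of labels.
#' @param traveler Named logical vector: protein id -> traveler flag.
#' @return An object of class `snl_annotations`.
#' @export
annotation_db <- function(labels = list(), traveler = logical()) {
  vocab <- subnuclear_compartments()
  labels <- lapply(labels, function(l) {
    canon <- vocab[match(tolower(l), tolower(vocab))]
    if (anyNA(canon)) {
      stop("unknown compartment label(s): ",
           paste(l[is.na(canon)], collapse = ", "),
           "; valid labels are: ", paste(vocab, collapse = ", "))
    }
    unique(canon)
  })
  if (length(labels) && (is.null(names(labels)) || any(!nzchar(names(labels))))) {
    stop("all annotated proteins must have non-empty ids")
  }
  if (any(lengths(labels) == 0L)) {
    stop("annotated label sets must be non-empty")
  }
  structure(list(labels = labels, traveler = traveler),
            class = "snl_annotations")
}

#' @export
print.snl_annotations <- function(x, ...) {
  cat("<snl_annotations> ", length(x$labels), " proteins with labels, ",
      sum(x$traveler), "/", length(x$traveler), " travelers\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and stripped of gap and whitespace characters.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence` (one row per
#'   record, file order preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("[-. \t*]", "", as.character(set)))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record(s) with empty sequence: ",
         paste(ids[empty], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Identify the header line of a PSI-BLAST ASCII checkpoint: the line whose
# whitespace tokens are 40 single residues (log-odds block then frequency
# block, both in alphabet order).
.pssm_header_line <- function(lines) {
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 40L && all(nchar(toks) == 1L) &&
        all(toks %in% aa_alphabet())) {
      return(i)
    }
  }
  stop("no PSSM column-header line (40 residue letters) found")
}

#' Read a PSI-BLAST ASCII PSSM into a profile
#'
#' Parses the classic PSI-BLAST checkpoint layout (header lines, then one
#' row per position carrying the position index, the query residue, 20
#' log-odds integers and 20 percentage columns). The percentage columns are
#' converted to conservation costs `-log(f)` with frequencies `f` floored at
#' a pseudo-frequency, so that fully conserved residues cost 0 and absent
#' residues cost `-log(pseudo_freq)`. The log-odds columns can be used
#' instead; they are rescaled per position to `max(s) - s` so costs stay
#' non-negative with 0 for the best-scoring residue.
#'
#' @param path Path to the ASCII PSSM.
#' @param columns `"freq"` (default) to use the percentage block,
#'   `"logodds"` for the log-odds block.
#' @param pseudo_freq Floor applied to frequencies before taking `-log`.
#' @return An `snl_profile` with the query sequence attached.
#' @export
read_pssm <- function(path, columns = c("freq", "logodds"),
                      pseudo_freq = 0.001) {
  columns <- match.arg(columns)
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  hdr <- .pssm_header_line(lines)
  rows <- list()
  residues <- character()
  last <- hdr
  for (i in seq((hdr + 1), length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break  # blank line ends the matrix block
    toks <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break  # trailer (K/lambda lines)
    if (length(toks) < 42L) {
      stop("PSSM line ", i, " has ", length(toks),
           " fields; expected at least 42 (last complete line: ", last, ")")
    }
    vals <- suppressWarnings(as.numeric(toks[3:42]))
    if (anyNA(vals)) stop("non-numeric PSSM cell on line ", i)
    pos <- as.integer(toks[1])
    if (pos != length(rows) + 1L) {
      stop("PSSM position index ", pos, " on line ", i,
           " does not follow row ", length(rows))
    }
    residues[pos] <- toks[2]
    rows[[pos]] <- vals
    last <- i
  }
  if (length(rows) == 0L) stop("PSSM matrix block is empty in ", path)
  m <- do.call(rbind, rows)
  if (columns == "freq") {
    f <- m[, 21:40, drop = FALSE] / 100
    scores <- -log(pmax(f, pseudo_freq))
    scores[scores < 0] <- 0
  } else {
    lo <- m[, 1:20, drop = FALSE]
    scores <- sweep(-lo, 1, -apply(lo, 1, max), "+")
  }
  id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  new_profile(id, scores, source = "pssm-derived",
              sequence = paste(residues, collapse = ""))
}

#' Write a PSI-BLAST-style ASCII PSSM
#'
#' Writes the classic checkpoint layout from integer percentage columns, so
#' that synthetic profiles can be pushed through [read_pssm()]. Log-odds
#' columns are emitted as zeros (they are not used by the default reader).
#'
#' @param id Protein id (written into the header comment).
#' @param sequence Query sequence, one residue per matrix row.
#' @param percentages `L x 20` matrix of integer percentages (rows need not
#'   sum to exactly 100).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(id, sequence, percentages, path) {
  percentages <- as.matrix(percentages)
  stopifnot(ncol(percentages) == 20L,
            nrow(percentages) == nchar(sequence))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed for", id),
    paste(" ", paste(rep(aa_alphabet(), 2), collapse = "  "))
  ), con)
  res <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(percentages))) {
    writeLines(sprintf("%5d %s %s %s", i, res[i],
                       paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
                       paste(sprintf("%4d", round(percentages[i, ])),
                             collapse = " ")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read profiles from the native tab-separated profile format
#'
#' The native format stores one or more profiles as rows
#' `id <TAB> position <TAB> cost_A ... cost_V` with a header line naming the
#' 20 cost columns in alphabet order. Lines starting with `#` are ignored.
#'
#' @param path Path to the profile TSV.
#' @return Named list of `snl_profile` objects.
#' @export
read_profiles_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  need <- c("id", "position", aa_alphabet())
  if (!all(need %in% colnames(df))) {
    stop("profile TSV must have columns: id, position, ",
         paste(aa_alphabet(), collapse = ", "))
  }
  out <- lapply(split(df, factor(df$id, levels = unique(df$id))), function(d) {
    d <- d[order(d$position), ]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("profile ", d$id[1], ": positions must be 1..L without gaps")
    }
    m <- as.matrix(d[, aa_alphabet()])
    rownames(m) <- NULL
    new_profile(as.character(d$id[1]), m, source = "synthetic")
  })
  out
}

#' Write profiles to the native tab-separated profile format
#'
#' @param profiles A single `snl_profile` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  if (inherits(profiles, "snl_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(id = p$id, position = seq_len(nrow(p$scores)),
               p$scores, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignment hits from BLAST-style tabular output
#'
#' Accepts the standard 12-column tabular layout (query, subject, percent
#' identity, ..., E-value, bit score); column positions are configurable for
#' reduced layouts.
#'
#' @param path Path to the tab-separated hit table.
#' @param cols Named integer vector giving 1-based column indices for
#'   `query`, `subject`, `pident` and `evalue`.
#' @return Data frame with columns `query`, `subject`, `pide`, `evalue`, in
#'   file order.
#' @export
read_blast_tab <- function(path,
                           cols = c(query = 1L, subject = 2L, pident = 3L,
                                    evalue = 11L)) {
  stopifnot(all(c("query", "subject", "pident", "evalue") %in% names(cols)))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      pide = numeric(), evalue = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i, what) {
    f <- fields[[i]]
    if (max(cols) > length(f)) {
      stop("line ", lineno[i], ": expected at least ", max(cols), " columns")
    }
    f[cols[[what]]]
  }
  n <- length(fields)
  query <- vapply(seq_len(n), get, character(1), what = "query")
  subject <- vapply(seq_len(n), get, character(1), what = "subject")
  pide <- suppressWarnings(as.numeric(
    vapply(seq_len(n), get, character(1), what = "pident")))
  evalue <- suppressWarnings(as.numeric(
    vapply(seq_len(n), get, character(1), what = "evalue")))
  bad <- which(is.na(pide) | is.na(evalue))
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": non-numeric percent identity or E-value")
  }
  bad <- which(pide < 0 | pide > 100 | evalue < 0)
  if (length(bad)) {
    stop("line ", lineno[bad[1]],
         ": percent identity must be in [0,100] and E-value non-negative")
  }
  data.frame(query = query, subject = subject, pide = pide, evalue = evalue)
}

#' Read compartment annotations (and optionally traveler flags)
#'
#' The annotation table has one mapping per line, `protein_id <TAB> label`,
#' with labels from the 13-compartment vocabulary (case-insensitive);
#' duplicate lines are merged. The optional traveler table has lines
#' `protein_id <TAB> flag` with flag in `{0, 1, true, false}`.
#'
#' @param labels_path Path to the label TSV.
#' @param traveler_path Optional path to the traveler TSV.
#' @return An `snl_annotations` object.
#' @export
read_annotations <- function(labels_path, traveler_path = NULL) {
  df <- read.delim(labels_path, header = FALSE, comment.char = "#",
                   col.names = c("id", "label"),
                   colClasses = "character")
  labels <- lapply(split(df$label, df$id), unique)
  traveler <- logical()
  if (!is.null(traveler_path)) {
    tf <- read.delim(traveler_path, header = FALSE, comment.char = "#",
                     col.names = c("id", "flag"), colClasses = "character")
    tf <- tf[!duplicated(tf$id), ]
    flag <- tolower(tf$flag) %in% c("1", "true", "yes")
    bad <- !(tolower(tf$flag) %in% c("0", "1", "true", "false", "yes", "no"))
    if (any(bad)) stop("unparsable traveler flag(s): ",
                       paste(unique(tf$flag[bad]), collapse = ", "))
    traveler <- setNames(flag, tf$id)
  }
  annotation_db(labels = labels, traveler = traveler)
}

#' Read a protein-protein interaction edge list
#'
#' Expects at least two tab-separated id columns; optional evidence columns
#' `is_direct` (0/1), `y2h` (0/1) and `n_pubmed` (integer) support the
#' binary-direct evidence filter: keep an edge only when it is a direct
#' physical interaction and either yeast-two-hybrid validated or supported
#' by at least two publications. The filter is applied when the evidence
#' columns are present and `apply_evidence_filter` is `TRUE`. Self-loops are
#' kept in the returned table but flagged, and are dropped from all network
#' statistics downstream.
#'
#' @param path Path to the edge TSV (header line required).
#' @param apply_evidence_filter Apply the evidence filter if possible.
#' @return Data frame with columns `a`, `b`, `self` and any evidence
#'   columns.
#' @export
read_edges <- function(path, apply_evidence_filter = TRUE) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L) stop("edge table needs at least two columns")
  names(df)[1:2] <- c("a", "b")
  df$a <- as.character(df$a)
  df$b <- as.character(df$b)
  has_evidence <- all(c("is_direct", "y2h", "n_pubmed") %in% names(df))
  if (apply_evidence_filter && has_evidence) {
    keep <- df$is_direct == 1 & (df$y2h == 1 | df$n_pubmed >= 2)
    df <- df[keep, , drop = FALSE]
  }
  df$self <- df$a == df$b
  if (any(df$self)) {
    warning(sum(df$self), " self-loop edge(s) flagged; they are excluded ",
            "from interaction statistics")
  }
  rownames(df) <- NULL
  df
}

#' Read a protein-to-GO-term table
#'
#' One mapping per line: `protein_id <TAB> go_term`; duplicates are merged.
#'
#' @param path Path to the GO TSV.
#' @return Named list: protein id -> character vector of GO terms.
#' @export
read_go <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("id", "term"), colClasses = "character")
  lapply(split(df$term, df$id), unique)
}
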