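# Sequence records: named amino-acid sequences with optional
# signal-peptide / mature-chain annotation.

#' Standard one-letter amino-acid codes
#'
#' The 20 standard residues, in the conventional alphabetical-by-code
#' order used throughout the package.
#' @keywords internal
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a sequence record
#'
#' A `seq_record` holds one amino-acid sequence together with an
#' identifier, a free-text description, and optional 1-based inclusive
#' signal-peptide and mature-chain intervals.  When both intervals are
#' present they must be disjoint, contiguous, and jointly cover the
#' whole sequence (the precursor layout of a secreted protein).
#'
#' @param identifier Short identifier (FASTA header word).
#' @param residues Amino-acid sequence, one-letter codes.  Lower case is
#'   accepted and upper-cased.
#' @param description Free-text description (may be empty).
#' @param signal_range Optional integer vector `c(start, end)`, 1-based
#'   inclusive, for the signal peptide.
#' @param mature_range Optional integer vector `c(start, end)` for the
#'   mature chain.
#' @param allow_extended If `TRUE`, the placeholder code `X` is accepted
#'   in addition to the 20 standard residues.  Off by default because
#'   downstream mass and accessibility tables are only defined for the
#'   standard residues (plus DOPA).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(identifier, residues, description = "",
                       signal_range = NULL, mature_range = NULL,
                       allow_extended = FALSE) {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) {
    stop("sequence record '", identifier, "' has an empty sequence")
  }
  valid <- AA_CODES
  if (allow_extended) valid <- c(valid, "X")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), valid)
  if (length(bad) > 0L) {
    stop("record '", identifier, "' contains non-amino-acid character(s): ",
         paste(sQuote(bad), collapse = ", "))
  }
  n <- nchar(residues)
  check_range <- function(r, what) {
    if (is.null(r)) return(NULL)
    r <- as.integer(r)
    if (length(r) != 2L || anyNA(r) || r[1L] < 1L || r[2L] > n || r[1L] > r[2L]) {
      stop(what, " range must be a valid 1-based interval within 1..", n)
    }
    r
  }
  signal_range <- check_range(signal_range, "signal")
  mature_range <- check_range(mature_range, "mature")
  if (!is.null(signal_range) && !is.null(mature_range)) {
    covered <- sort(c(seq.int(signal_range[1L], signal_range[2L]),
                      seq.int(mature_range[1L], mature_range[2L])))
    if (!identical(covered, seq_len(n))) {
      stop("signal and mature ranges must be disjoint, contiguous, ",
           "and together cover 1..", n)
    }
  }
  structure(
    list(identifier = identifier, description = description,
         residues = residues, signal_range = signal_range,
         mature_range = mature_range),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$identifier, "  (", nchar(x$residues), " aa)\n",
      sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  if (!is.null(x$signal_range)) {
    cat("  signal: ", x$signal_range[1L], "-", x$signal_range[2L], "\n",
        sep = "")
  }
  if (!is.null(x$mature_range)) {
    cat("  mature: ", x$mature_range[1L], "-", x$mature_range[2L], "\n",
        sep = "")
  }
  seq <- x$residues
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat("  ", seq, "\n", sep = "")
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

#' Read sequences from a FASTA file
#'
#' Parses a FASTA file (wrapped or unwrapped lines) into a list of
#' [seq_record()] objects, one per `>` header, in file order.
#' Sequences are upper-cased and whitespace is stripped; any character
#' outside the 20 standard one-letter codes is an error naming the
#' offending character and record.
#'
#' @param path Path to a FASTA file.
#' @param allow_extended Passed to [seq_record()].
#' @return List of `seq_record`.
#' @export
read_fasta <- function(path, allow_extended = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    s <- as.character(set[[i]])
    if (!nzchar(gsub("[[:space:]]", "", s))) {
      stop("record '", id, "' in '", path, "' has an empty sequence")
    }
    out[[i]] <- seq_record(id, s, description = desc,
                           allow_extended = allow_extended)
  }
  out
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [seq_record()] (or a single record).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description)) {
      paste(r$identifier, r$description)
    } else r$identifier
    body <- substring(r$residues,
                      seq(1L, nchar(r$residues), by = width),
                      pmin(seq(1L, nchar(r$residues), by = width) + width - 1L,
                           nchar(r$residues)))
    c(paste0(">", header), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Split a precursor into signal peptide and mature chain
#'
#' Cuts a precursor record after `signal_length` residues, returning the
#' signal peptide and the mature chain as two standalone records with
#' their ranges annotated on the parent numbering recorded in the
#' descriptions.
#'
#' @param record A [seq_record()].
#' @param signal_length Number of N-terminal residues in the signal
#'   peptide; must satisfy `0 < signal_length < length(record)`.
#' @return A list with elements `signal` and `mature`.
#' @export
split_precursor <- function(record, signal_length) {
  stopifnot(inherits(record, "seq_record"))
  signal_length <- as.integer(signal_length)
  n <- nchar(record$residues)
  if (is.na(signal_length) || signal_length <= 0L || signal_length >= n) {
    stop("signal_length must satisfy 0 < signal_length < ", n,
         " (got ", signal_length, ")")
  }
  sig <- seq_record(
    paste0(record$identifier, "_signal"),
    substr(record$residues, 1L, signal_length),
    description = sprintf("signal peptide, precursor residues 1-%d",
                          signal_length)
  )
  mat <- seq_record(
    paste0(record$identifier, "_mature"),
    substr(record$residues, signal_length + 1L, n),
    description = sprintf("mature chain, precursor residues %d-%d",
                          signal_length + 1L, n)
  )
  list(signal = sig, mature = mat)
}

#' Count occurrences of one residue type in a sequence
#'
#' @param record A [seq_record()].
#' @param amino_acid A single one-letter code among the 20 standard
#'   residues.
#' @return Integer count.
#' @export
count_residue <- function(record, amino_acid) {
  stopifnot(inherits(record, "seq_record"))
  if (!is.character(amino_acid) || length(amino_acid) != 1L ||
      !(toupper(amino_acid) %in% AA_CODES)) {
    stop("amino_acid must be one of the 20 standard one-letter codes")
  }
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1L]]
  sum(chars == toupper(amino_acid))
}

#' Bundled MFP3 and CsgA precursor sequences
#'
#' Returns the two precursor sequences bundled with the package as
#' [seq_record()] objects: the Mytilus galloprovincialis foot protein 3
#' precursor (24-residue signal peptide + 46-residue mature chain) and
#' the E. coli major curlin subunit CsgA precursor (20-residue signal
#' peptide + mature chain).  These are the parent sequences of the
#' CsgA-MFP3 adhesive chimera.
#'
#' @return Named list with elements `mfp3` and `csga`.
#' @export
bundled_precursors <- function() {
  dir <- system.file("extdata", package = "dopasight", mustWork = TRUE)
  mfp3 <- read_fasta(file.path(dir, "mfp3_precursor.fasta"))[[1L]]
  csga <- read_fasta(file.path(dir, "csga_precursor.fasta"))[[1L]]
  n_m <- nchar(mfp3$residues)
  n_c <- nchar(csga$residues)
  mfp3 <- seq_record(mfp3$identifier, mfp3$residues, mfp3$description,
                     signal_range = c(1L, 24L), mature_range = c(25L, n_m))
  csga <- seq_record(csga$identifier, csga$residues, csga$description,
                     signal_range = c(1L, 20L), mature_range = c(21L, n_c))
  list(mfp3 = mfp3, csga = csga)
}
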