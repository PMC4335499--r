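#' Read a homologue alignment and map columns to reference numbering
#'
#' Parses a multiple sequence alignment (Clustal or aligned FASTA) of a
#' reference protein and its homologues and builds the map from alignment
#' columns to 1-based reference residue positions by walking the reference
#' row: columns where the reference carries a gap map to nothing.
#'
#' @param path Path to the alignment file.
#' @param reference_id Identifier of the reference sequence row.
#' @param format \code{"auto"} (sniffs Clustal headers), \code{"fasta"} or
#'   \code{"clustal"}.
#' @return An object of class \code{"homolog_alignment"}: a list with
#'   \code{sequences} (named character vector of equal-length aligned
#'   strings), \code{reference_id}, and \code{column_to_refpos} (integer
#'   vector over columns, \code{NA} at reference-gap columns).
#' @export
read_alignment <- function(path, reference_id,
                           format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^(CLUSTAL|MUSCLE)", first, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  homolog_alignment(seqs, reference_id)
}

#' Construct a homologue alignment from aligned strings
#'
#' @param sequences Named character vector of aligned residue strings
#'   (gaps \code{"-"}), all the same length.
#' @param reference_id Name of the reference row.
#' @return See \code{\link{read_alignment}}.
#' @export
homolog_alignment <- function(sequences, reference_id) {
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("sequences must be named")
  if (length(unique(nchar(sequences))) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (!reference_id %in% names(sequences))
    stop("reference '", reference_id, "' not present in the alignment")
  ref <- strsplit(toupper(sequences[[reference_id]]), "")[[1]]
  col_map <- rep(NA_integer_, length(ref))
  nongap <- ref != "-"
  col_map[nongap] <- seq_len(sum(nongap))
  structure(list(sequences = toupper(sequences),
                 reference_id = reference_id,
                 column_to_refpos = col_map),
            class = "homolog_alignment")
}

#' @export
print.homolog_alignment <- function(x, ...) {
  cat("Alignment of ", length(x$sequences), " sequences, ",
      nchar(x$sequences[[1]]), " columns (",
      sum(!is.na(x$column_to_refpos)),
      " reference residues); reference: ", x$reference_id, "\n", sep = "")
  invisible(x)
}

# residues treated as unscorable in homologue rows: gaps and ambiguity codes
.SKIP_RESIDUES <- c("-", ".", "X", "B", "Z", "J", "U", "O", "*")

.window_columns <- function(aln, window) {
  npos <- sum(!is.na(aln$column_to_refpos))
  if (window[1] < 1 || window[2] > npos || window[1] > window[2])
    stop("window [", window[1], ", ", window[2],
         "] outside reference length ", npos)
  which(!is.na(aln$column_to_refpos) &
          aln$column_to_refpos >= window[1] &
          aln$column_to_refpos <= window[2])
}

#' Catalogue natural substitutions in a reference window
#'
#' Walks every homologue over the reference-position window and records
#' each single amino acid difference ("natural substitution") relative to
#' the reference, together with the homologues carrying it. A homologue
#' gap at a reference position is not a substitution, insertions relative
#' to the reference contribute nothing, and ambiguity codes are skipped.
#'
#' @param aln A \code{\link{homolog_alignment}}.
#' @param window Length-2 integer vector of inclusive 1-based reference
#'   positions bounding the scanned region.
#' @return Data frame of class \code{"substitution_catalogue"} with
#'   columns \code{position}, \code{ref_aa}, \code{alt_aa} and
#'   \code{homolog_ids} (comma-joined), one row per distinct substitution,
#'   ordered by position then alternative residue.
#' @export
extract_natural_substitutions <- function(aln, window) {
  cols <- .window_columns(aln, window)
  refrow <- strsplit(aln$sequences[[aln$reference_id]], "")[[1]]
  others <- setdiff(names(aln$sequences), aln$reference_id)
  recs <- list()
  for (h in others) {
    row <- strsplit(aln$sequences[[h]], "")[[1]]
    diff <- cols[row[cols] != refrow[cols] &
                   !(row[cols] %in% .SKIP_RESIDUES)]
    if (length(diff))
      recs[[h]] <- data.frame(position = aln$column_to_refpos[diff],
                              ref_aa = refrow[diff], alt_aa = row[diff],
                              homolog = h, stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    out <- data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), homolog_ids = character(),
                      stringsAsFactors = FALSE)
  } else {
    all <- do.call(rbind, recs)
    key <- paste(all$position, all$ref_aa, all$alt_aa)
    agg <- lapply(split(all, key), function(d) {
      data.frame(position = d$position[1], ref_aa = d$ref_aa[1],
                 alt_aa = d$alt_aa[1],
                 homolog_ids = paste(sort(unique(d$homolog)),
                                     collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out <- out[order(out$position, out$alt_aa), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, window = as.integer(window),
            reference_id = aln$reference_id,
            class = c("substitution_catalogue", "data.frame"))
}

#' @export
print.substitution_catalogue <- function(x, ...) {
  w <- attr(x, "window")
  cat("Natural-substitution catalogue: ", nrow(x), " entries over reference positions ",
      w[1], "-", w[2], "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Differences between the reference and one homologue
#'
#' @param aln A \code{\link{homolog_alignment}}.
#' @param homolog_id Homologue to compare against the reference.
#' @param window Inclusive reference-position window.
#' @return Data frame with \code{position}, \code{ref_aa}, \code{alt_aa},
#'   ordered by position.
#' @export
pairwise_differences <- function(aln, homolog_id, window) {
  if (!homolog_id %in% names(aln$sequences))
    stop("unknown homologue '", homolog_id, "'")
  cols <- .window_columns(aln, window)
  refrow <- strsplit(aln$sequences[[aln$reference_id]], "")[[1]]
  row <- strsplit(aln$sequences[[homolog_id]], "")[[1]]
  diff <- cols[row[cols] != refrow[cols] &
                 !(row[cols] %in% .SKIP_RESIDUES)]
  data.frame(position = aln$column_to_refpos[diff],
             ref_aa = refrow[diff], alt_aa = row[diff],
             stringsAsFactors = FALSE)
}

#' Percent identity of a homologue to the reference over a window
#'
#' Identity is counted over reference (non-gap) window columns; a
#' homologue gap facing a reference residue counts as a mismatch.
#'
#' @inheritParams pairwise_differences
#' @return Percent identity in [0, 100].
#' @export
percent_identity <- function(aln, homolog_id, window) {
  if (!homolog_id %in% names(aln$sequences))
    stop("unknown homologue '", homolog_id, "'")
  cols <- .window_columns(aln, window)
  refrow <- strsplit(aln$sequences[[aln$reference_id]], "")[[1]]
  row <- strsplit(aln$sequences[[homolog_id]], "")[[1]]
  100 * sum(row[cols] == refrow[cols]) / length(cols)
}

#' Per-homologue substitution sets
#'
#' Inverts the catalogue into a map from homologue id to the set of
#' substitutions that homologue carries, in \code{"K180E"} notation. This
#' is the structure the epistasis co-occurrence partition consumes: a pair
#' of substitutions co-occurs only if some single homologue carries both.
#'
#' @param cat A \code{\link{extract_natural_substitutions}} catalogue.
#' @return Named list of character vectors.
#' @export
per_homolog_substitution_sets <- function(cat) {
  if (!nrow(cat)) return(list())
  labels <- substitution_label(cat$position, cat$ref_aa, cat$alt_aa)
  ids <- strsplit(cat$homolog_ids, ",", fixed = TRUE)
  long <- data.frame(homolog = unlist(ids),
                     label = rep(labels, lengths(ids)),
                     stringsAsFactors = FALSE)
  lapply(split(long$label, long$homolog), unique)
}

#' Substitution label helpers
#'
#' \code{substitution_label} builds \code{"A185K"}-style labels;
#' \code{parse_substitutions} splits a semicolon-joined variant
#' substitution string into a data frame of (position, ref_aa, alt_aa),
#' with \code{"*"} allowed as a stop alternative.
#'
#' @param position Integer vector of 1-based reference positions.
#' @param ref_aa,alt_aa Amino-acid letters.
#' @return A character vector of labels.
#' @export
substitution_label <- function(position, ref_aa, alt_aa) {
  paste0(ref_aa, position, alt_aa)
}

#' @rdname substitution_label
#' @param x Character vector like \code{"A185K;L186M"} (empty string =
#'   no substitutions).
#' @export
parse_substitutions <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x))
    return(data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), stringsAsFactors = FALSE))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z*])$", parts))
  if (any(lengths(m) != 4L))
    stop("malformed substitution string: ", x)
  out <- data.frame(position = as.integer(vapply(m, `[`, "", 3L)),
                    ref_aa = vapply(m, `[`, "", 2L),
                    alt_aa = vapply(m, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  if (any(out$ref_aa == out$alt_aa))
    stop("substitution with identical reference and alternative: ", x)
  if (is.unsorted(out$position, strictly = TRUE))
    stop("substitution positions must be strictly increasing: ", x)
  out
}
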