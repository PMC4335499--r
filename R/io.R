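# Tab-separated readers/writers for the pipeline's file dialects.

.read_tsv <- function(path, required) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop(path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  d
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write pipeline tables
#'
#' Tab-separated dialects used throughout: a variant count table
#' (\code{variant_id substitutions is_synonymous input_count
#' selected_count}; substitutions semicolon-joined \code{A185K} labels,
#' empty for none, \code{*} for stops), a per-residue fractional-ASA
#' table (\code{position fractional_asa}), an unordered spatial-adjacency
#' pair table (\code{position_i position_j}), and a long ancestral
#' posterior table (\code{node position aa probability}).
#'
#' @param path File path.
#' @return A data frame with the dialect's columns; counts and flags are
#'   coerced to the documented types.
#' @export
read_count_table <- function(path) {
  d <- .read_tsv(path, c("variant_id", "substitutions", "is_synonymous",
                         "input_count", "selected_count"))
  d$substitutions[is.na(d$substitutions)] <- ""
  d$is_synonymous <- as.logical(d$is_synonymous)
  d$input_count <- as.integer(d$input_count)
  d$selected_count <- as.integer(d$selected_count)
  d
}

#' @rdname read_count_table
#' @param records Data frame in the count-table dialect.
#' @export
write_count_table <- function(records, path) .write_tsv(records, path)

#' @rdname read_count_table
#' @param table A score table.
#' @export
write_score_table <- function(table, path) {
  .write_tsv(as.data.frame(table)[, c("variant_id", "linear_ratio",
                                      "log2_score", "passed_filter",
                                      "filter_reason")], path)
}

#' @rdname read_count_table
#' @param cat A substitution catalogue.
#' @export
write_catalogue <- function(cat, path) {
  .write_tsv(as.data.frame(cat), path)
}

#' @rdname read_count_table
#' @export
read_asa_table <- function(path) {
  d <- .read_tsv(path, c("position", "fractional_asa"))
  d$position <- as.integer(d$position)
  d$fractional_asa <- as.numeric(d$fractional_asa)
  d
}

#' @rdname read_count_table
#' @export
read_adjacency_table <- function(path) {
  d <- .read_tsv(path, c("position_i", "position_j"))
  d$position_i <- as.integer(d$position_i)
  d$position_j <- as.integer(d$position_j)
  d
}

#' @rdname read_count_table
#' @export
read_posterior_table <- function(path) {
  d <- .read_tsv(path, c("node", "position", "aa", "probability"))
  d$position <- as.integer(d$position)
  d$probability <- as.numeric(d$probability)
  d
}

#' @rdname read_count_table
#' @param aln A homologue alignment to write as aligned FASTA.
#' @export
write_alignment_fasta <- function(aln, path) {
  lines <- character(0)
  for (id in names(aln$sequences))
    lines <- c(lines, paste0(">", id), aln$sequences[[id]])
  writeLines(lines, path)
  invisible(path)
}
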