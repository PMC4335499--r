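#' Call an ancestral state from a posterior probability vector
#'
#' Applies the probability-cutoff rule for accepting reconstructed
#' ancestral amino acids: a single call when the most probable residue
#' exceeds 0.7; otherwise a pair call when the two most probable residues
#' each reach 0.3 and jointly exceed 0.75; otherwise ambiguous. A tie
#' between the second and third most probable residues leaves the pair
#' undefined, so the call is ambiguous.
#'
#' @param probs Named numeric vector of posterior probabilities over
#'   amino acids (non-negative, summing to at most 1 within tolerance;
#'   omitted residues count as 0).
#' @param single_min Exclusive lower bound for a single-residue call.
#' @param pair_each_min Inclusive per-residue bound for a pair call.
#' @param pair_sum_min Exclusive bound on the pair's summed probability.
#' @return List of class \code{"ancestral_call"}: \code{call} one of
#'   \code{"single"}, \code{"pair"}, \code{"ambiguous"}; \code{aa}
#'   (length 1, 2 or 0, ordered by descending probability) and
#'   \code{probabilities}.
#' @export
call_ancestral_state <- function(probs, single_min = 0.7,
                                 pair_each_min = 0.3,
                                 pair_sum_min = 0.75) {
  if (is.null(names(probs)) || anyNA(probs) || any(probs < 0))
    stop("probs must be a named, non-negative probability vector")
  if (sum(probs) > 1 + 1e-9)
    stop("probabilities sum to more than 1")
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]
  out <- if (p[1] > single_min) {
    list(call = "single", aa = names(p)[1], probabilities = p[1])
  } else if (length(p) >= 2 &&
             p[1] >= pair_each_min && p[2] >= pair_each_min &&
             p[1] + p[2] > pair_sum_min &&
             !(length(p) >= 3 && p[3] == p[2])) {
    list(call = "pair", aa = names(p)[1:2], probabilities = p[1:2])
  } else {
    list(call = "ambiguous", aa = character(), probabilities = numeric())
  }
  class(out) <- "ancestral_call"
  out
}

#' @export
print.ancestral_call <- function(x, ...) {
  cat("Ancestral call:", x$call,
      if (length(x$aa)) paste0("(", paste(x$aa, collapse = "/"), ")"), "\n")
  invisible(x)
}

#' Call ancestral states for a posterior table
#'
#' @param posteriors Long-format data frame with columns \code{node},
#'   \code{position}, \code{aa}, \code{probability}.
#' @param ... Cutoffs passed to \code{\link{call_ancestral_state}}.
#' @return Data frame with one row per (node, position): \code{call},
#'   \code{aa_primary}, \code{aa_secondary} (NA unless a pair call).
#' @export
call_ancestral_states <- function(posteriors, ...) {
  req <- c("node", "position", "aa", "probability")
  stopifnot(all(req %in% names(posteriors)))
  groups <- split(posteriors,
                  list(posteriors$node, posteriors$position), drop = TRUE)
  rows <- lapply(groups, function(g) {
    p <- g$probability
    names(p) <- g$aa
    cl <- call_ancestral_state(p, ...)
    data.frame(node = g$node[1], position = g$position[1],
               call = cl$call,
               aa_primary = if (length(cl$aa) >= 1) cl$aa[1] else NA_character_,
               aa_secondary = if (length(cl$aa) >= 2) cl$aa[2] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$node, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relate per-homologue deleterious burden to sequence divergence
#'
#' Counts, for each homologue, how many of its natural substitutions are
#' classified strongly deleterious in the reference background, and
#' correlates that burden with divergence (100 - percent identity over
#' the analysis window) by Spearman rank correlation. Divergence is
#' proxied by window identity because branch lengths are upstream
#' outputs this stage does not consume.
#'
#' @param cat A substitution catalogue.
#' @param classified The catalogue after \code{\link{classify}} (same
#'   rows, with \code{category}).
#' @param identities Named numeric vector of percent identity per
#'   homologue (e.g. from \code{\link{percent_identity}}).
#' @return List with \code{per_homolog} (data frame: homolog,
#'   strongly_deleterious count, percent_identity, divergence),
#'   \code{rho} and \code{p.value}.
#' @export
deleterious_burden_vs_divergence <- function(cat, classified, identities) {
  sets <- per_homolog_substitution_sets(cat)
  strong <- substitution_label(classified$position, classified$ref_aa,
                               classified$alt_aa)[
    classified$category == "strongly_deleterious"]
  homs <- names(identities)
  burden <- vapply(homs, function(h) {
    s <- sets[[h]]
    if (is.null(s)) 0L else sum(s %in% strong)
  }, 0L)
  d <- data.frame(homolog = homs,
                  strongly_deleterious = burden,
                  percent_identity = as.numeric(identities),
                  divergence = 100 - as.numeric(identities),
                  stringsAsFactors = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(d$strongly_deleterious, d$divergence,
                    method = "spearman"))
  list(per_homolog = d, rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Read a newick tree to order homologues in reports
#'
#' Only the topology and tip labels are used (for presentation order);
#' branch lengths are ignored.
#'
#' @param path Path to a newick file.
#' @return Character vector of tip labels in tree order.
#' @export
read_tree_order <- function(path) {
  tree <- ape::read.tree(path)
  tree$tip.label
}
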