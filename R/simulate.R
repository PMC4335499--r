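#' Configuration for the synthetic study generator
#'
#' The defaults emulate the reference study design: a 75-residue scanned
#' window, 52 homologues spanning roughly 55-88 percent identity, a
#' 210-entry natural-substitution catalogue of which 17 substitutions are
#' strongly and 45 mildly deleterious in the reference background, one
#' human-like homologue differing at exactly 25 positions, planted
#' compensatory pairs with positive epistasis, and growth selection read
#' out by multinomial sequencing at both time points.
#'
#' @param seed Integer seed (mandatory); every stochastic operation is a
#'   pure function of (config, seed).
#' @param window_length Number of reference residues scanned.
#' @param n_homologs Number of homologue sequences.
#' @param n_catalogue Number of distinct natural substitutions planted.
#' @param n_strong,n_mild Planted strongly / mildly deleterious counts;
#'   the remainder of the catalogue is non-deleterious.
#' @param strong_fitness,mild_fitness,neutral_fitness Length-2 ranges the
#'   per-substitution relative growth rates are drawn from (1 =
#'   wild-type). The defaults keep each category clear of the -0.5 and
#'   -0.15 log2 classification bounds.
#' @param identity_range Percent-identity span of the homologue set
#'   (least to most diverged).
#' @param human_diffs Differences carried by the designated human-like
#'   homologue (id \code{"human_like"}).
#' @param n_compensatory Number of planted (deleterious, compensator)
#'   pairs co-occurring in designated homologues.
#' @param epistasis_effect Linear-scale epistasis added to the planted
#'   compensatory double mutants.
#' @param cooccurring_epistasis Range of the small positive epistasis
#'   given to other co-occurring double mutants (the non-co-occurring
#'   ones get none).
#' @param n_synonymous Synonymous variants (fitness exactly 1).
#' @param n_double_cooccurring,n_double_noncooccurring Double mutants
#'   drawn from pairs that do / do not co-occur in a single homologue.
#' @param depth Sequencing reads per library time point.
#' @param generations Selection generations; at the default 1 a planted
#'   fitness equals its expected linear enrichment ratio.
#' @param dirichlet_concentration Concentration of the Dirichlet library
#'   composition (smaller = more uneven variant representation).
#' @param wt_weight Multiplier on the wild-type's library weight.
#' @param n_contact,n_proximal,n_buried Contact-site, spatially proximal
#'   and buried position counts for the side tables.
#' @param asa_noise Standard deviation of noise added to the emitted
#'   fractional ASA values (0 keeps them consistent with burial truth).
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed,
                              window_length = 75,
                              n_homologs = 52,
                              n_catalogue = 210,
                              n_strong = 17,
                              n_mild = 45,
                              strong_fitness = c(0.35, 0.62),
                              mild_fitness = c(0.72, 0.88),
                              neutral_fitness = c(0.95, 1.05),
                              identity_range = c(55, 88),
                              human_diffs = 25,
                              n_compensatory = 3,
                              epistasis_effect = 0.3,
                              cooccurring_epistasis = c(0.02, 0.10),
                              n_synonymous = 200,
                              n_double_cooccurring = 120,
                              n_double_noncooccurring = 150,
                              depth = 1e6,
                              generations = 1,
                              dirichlet_concentration = 50,
                              wt_weight = 50,
                              n_contact = 8,
                              n_proximal = 5,
                              n_buried = 25,
                              asa_noise = 0) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$depth > 0, cfg$n_strong + cfg$n_mild <= cfg$n_catalogue,
            cfg$n_catalogue <= cfg$window_length * 19,
            cfg$human_diffs <= cfg$window_length)
  class(cfg) <- "simulation_config"
  cfg
}

.runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Simulate a homologue set with planted natural substitutions
#'
#' Draws a uniform-random reference sequence, a catalogue of distinct
#' substitutions with planted fitness categories, and homologues whose
#' substitution counts scale with their divergence level. Strongly
#' deleterious substitutions are placed preferentially in diverged
#' homologues (so deleterious burden grows with divergence), compensatory
#' pair members are placed together in designated homologues, and every
#' catalogue entry is carried by at least one homologue. The alignment is
#' gap-free.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{alignment} (a
#'   \code{\link{homolog_alignment}}) and \code{truth}: the catalogue
#'   with fitness and category, per-homologue substitution sets,
#'   compensatory pairs and divergence targets.
#' @export
simulate_homologs <- function(config) {
  set.seed(config$seed)
  L <- config$window_length
  aa <- .AA20
  reference <- sample(aa, L, replace = TRUE)

  # distinct (position, ref, alt) entries
  pool <- expand.grid(position = seq_len(L), alt_aa = aa,
                      stringsAsFactors = FALSE)
  pool$ref_aa <- reference[pool$position]
  pool <- pool[pool$alt_aa != pool$ref_aa, c("position", "ref_aa", "alt_aa")]
  pool <- pool[sample(nrow(pool), config$n_catalogue), , drop = FALSE]
  rownames(pool) <- NULL

  n <- config$n_catalogue
  cat_class <- rep("non_deleterious", n)
  cat_class[seq_len(config$n_strong)] <- "strongly_deleterious"
  cat_class[config$n_strong + seq_len(config$n_mild)] <- "mildly_deleterious"
  cat_class <- sample(cat_class)
  fitness <- numeric(n)
  fitness[cat_class == "strongly_deleterious"] <-
    .runif_range(sum(cat_class == "strongly_deleterious"), config$strong_fitness)
  fitness[cat_class == "mildly_deleterious"] <-
    .runif_range(sum(cat_class == "mildly_deleterious"), config$mild_fitness)
  fitness[cat_class == "non_deleterious"] <-
    .runif_range(sum(cat_class == "non_deleterious"), config$neutral_fitness)
  pool$category <- cat_class
  pool$fitness <- fitness
  pool$label <- substitution_label(pool$position, pool$ref_aa, pool$alt_aa)

  # divergence targets: differences per homologue, least to most diverged
  k_min <- round((1 - config$identity_range[2] / 100) * L)
  k_max <- round((1 - config$identity_range[1] / 100) * L)
  k <- round(seq(k_min, k_max, length.out = config$n_homologs))
  ids <- sprintf("hom%02d", seq_len(config$n_homologs))
  human <- which.min(abs(k - config$human_diffs))[1]
  k[human] <- config$human_diffs
  ids[human] <- "human_like"
  names(k) <- ids

  # entry weights per homologue: deleterious entries favour diverged rows
  div_frac <- (k - min(k)) / max(1, (max(k) - min(k)))
  assign <- stats::setNames(vector("list", length(ids)), ids)
  strong_idx <- which(pool$category == "strongly_deleterious")
  for (i in seq_along(ids)) {
    w <- rep(1, n)
    w[pool$category == "mildly_deleterious"] <- 0.25 + 0.5 * div_frac[i]
    w[strong_idx] <- 0.02 + 1.2 * div_frac[i]^3
    chosen <- integer(0)
    used_pos <- integer(0)
    cand <- if (n > 0) sample(n, prob = w) else integer(0)
    for (j in cand) {
      if (length(chosen) >= k[i]) break
      if (!(pool$position[j] %in% used_pos)) {
        chosen <- c(chosen, j)
        used_pos <- c(used_pos, pool$position[j])
      }
    }
    assign[[i]] <- chosen
  }

  # compensatory pairs: a strong entry plus a neutral partner, planted
  # together in one diverged homologue
  n_comp <- min(config$n_compensatory, length(strong_idx))
  comp <- NULL
  if (n_comp > 0) {
    del <- sample(strong_idx, n_comp)
    neutral_idx <- which(pool$category == "non_deleterious")
    comp_rows <- lapply(seq_len(n_comp), function(m) {
      partner <- sample(neutral_idx[pool$position[neutral_idx] !=
                                      pool$position[del[m]]], 1)
      host <- ids[order(-div_frac)][m]
      cur <- assign[[host]]
      for (idx in c(del[m], partner)) {
        clash <- cur[pool$position[cur] == pool$position[idx]]
        cur <- c(setdiff(cur, clash), idx)
      }
      assign[[host]] <<- cur
      data.frame(deleterious = pool$label[del[m]],
                 compensator = pool$label[partner],
                 homolog = host, stringsAsFactors = FALSE)
    })
    comp <- do.call(rbind, comp_rows)
  }

  # coverage: every catalogue entry must be carried somewhere
  carried <- unique(unlist(assign))
  for (j in setdiff(seq_len(n), carried)) {
    prefer <- if (pool$category[j] == "strongly_deleterious")
      ids[order(-div_frac)][seq_len(ceiling(length(ids) / 3))]
    else ids
    prefer <- setdiff(prefer, "human_like")
    for (h in sample(prefer)) {
      if (!(pool$position[j] %in% pool$position[assign[[h]]])) {
        assign[[h]] <- c(assign[[h]], j)
        break
      }
    }
  }

  seqs <- vapply(ids, function(h) {
    s <- reference
    rows <- assign[[h]]
    s[pool$position[rows]] <- pool$alt_aa[rows]
    paste(s, collapse = "")
  }, "")
  seqs <- c(reference = paste(reference, collapse = ""), seqs)
  aln <- homolog_alignment(seqs, "reference")

  per_homolog <- lapply(assign, function(rows) sort(pool$label[rows]))
  truth <- list(catalogue = pool,
                per_homolog = per_homolog,
                compensatory = comp,
                divergence_target = k,
                reference = paste(reference, collapse = ""))
  list(alignment = aln, truth = truth)
}

#' Simulate growth-selection sequencing counts
#'
#' Builds the variant library (wild type, synonymous variants, all
#' catalogue singles, and double mutants sampled from co-occurring and
#' non-co-occurring pairs), assigns each variant a relative growth rate
#' (doubles multiply their singles' rates plus any planted epistasis;
#' synonymous variants grow exactly like wild type), then simulates
#' selection as deterministic exponential growth of the library
#' composition with independent multinomial sequencing noise before and
#' after. Library composition is Dirichlet-distributed to model unequal
#' variant representation.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param truth The truth bundle from \code{\link{simulate_homologs}}.
#' @return List with \code{records} (a count table ready for
#'   \code{\link{compute_scores}}; wild type is \code{"WT"}) and
#'   \code{truth} extended with per-variant fitness and the planted
#'   double-mutant epistasis terms.
#' @export
simulate_selection_counts <- function(config, truth) {
  set.seed(config$seed + 1L)
  pool <- truth$catalogue
  fit <- stats::setNames(pool$fitness, pool$label)

  # enumerate co-occurring pairs (position-distinct, present together)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  co_pairs <- unique(do.call(rbind, lapply(truth$per_homolog, function(s) {
    if (length(s) < 2) return(NULL)
    idx <- t(utils::combn(sort(s), 2))
    data.frame(a = idx[, 1], b = idx[, 2], stringsAsFactors = FALSE)
  })))
  if (is.null(co_pairs))
    co_pairs <- data.frame(a = character(), b = character(),
                           stringsAsFactors = FALSE)
  pos_of <- stats::setNames(pool$position, pool$label)
  co_pairs <- co_pairs[pos_of[co_pairs$a] != pos_of[co_pairs$b], , drop = FALSE]
  co_keys <- pair_key(co_pairs$a, co_pairs$b)

  comp_keys <- character(0)
  if (!is.null(truth$compensatory))
    comp_keys <- pair_key(truth$compensatory$deleterious,
                          truth$compensatory$compensator)
  extra_co <- co_pairs[!(co_keys %in% comp_keys), , drop = FALSE]
  extra_co <- extra_co[sample(nrow(extra_co),
                              min(config$n_double_cooccurring,
                                  nrow(extra_co))), , drop = FALSE]

  # non-co-occurring pairs: rejection-sample label pairs never seen together
  all_co <- unique(co_keys)
  nc <- list(); tries <- 0
  while (nrow(pool) >= 4 &&
         length(nc) < config$n_double_noncooccurring && tries < 50) {
    tries <- tries + 1
    cand <- matrix(sample(pool$label, 2 * config$n_double_noncooccurring,
                          replace = TRUE), ncol = 2)
    ok <- cand[, 1] != cand[, 2] &
      pos_of[cand[, 1]] != pos_of[cand[, 2]] &
      !(pair_key(cand[, 1], cand[, 2]) %in% all_co)
    cand <- cand[ok, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      key <- pair_key(cand[r, 1], cand[r, 2])
      if (is.null(nc[[key]])) nc[[key]] <- cand[r, ]
      if (length(nc) >= config$n_double_noncooccurring) break
    }
  }
  non_co <- do.call(rbind, nc)

  mk_double <- function(a, b, eps, cooccurring) {
    pa <- pos_of[a]; pb <- pos_of[b]
    first <- ifelse(pa < pb, a, b)
    second <- ifelse(pa < pb, b, a)
    data.frame(substitutions = paste(first, second, sep = ";"),
               fitness = pmax(0.01, fit[a] * fit[b] + eps),
               epistasis_true = eps, cooccurring = cooccurring,
               stringsAsFactors = FALSE)
  }
  doubles <- list()
  if (length(comp_keys)) {
    doubles$comp <- mk_double(truth$compensatory$deleterious,
                              truth$compensatory$compensator,
                              rep(config$epistasis_effect,
                                  nrow(truth$compensatory)), TRUE)
  }
  if (nrow(extra_co)) {
    doubles$co <- mk_double(extra_co$a, extra_co$b,
                            .runif_range(nrow(extra_co),
                                         config$cooccurring_epistasis), TRUE)
  }
  if (!is.null(non_co) && nrow(non_co)) {
    doubles$non <- mk_double(non_co[, 1], non_co[, 2], rep(0, nrow(non_co)),
                             FALSE)
  }
  doubles <- do.call(rbind, doubles)
  if (is.null(doubles))
    doubles <- data.frame(substitutions = character(), fitness = numeric(),
                          epistasis_true = numeric(),
                          cooccurring = logical(), stringsAsFactors = FALSE)

  variants <- rbind(
    data.frame(variant_id = "WT", substitutions = "",
               is_synonymous = FALSE, fitness = 1,
               stringsAsFactors = FALSE),
    data.frame(variant_id = sprintf("syn%04d", seq_len(config$n_synonymous)),
               substitutions = "", is_synonymous = TRUE, fitness = 1,
               stringsAsFactors = FALSE),
    data.frame(variant_id = paste0("s_", pool$label),
               substitutions = pool$label, is_synonymous = FALSE,
               fitness = pool$fitness, stringsAsFactors = FALSE),
    if (nrow(doubles)) data.frame(
      variant_id = sprintf("d%04d", seq_len(nrow(doubles))),
      substitutions = doubles$substitutions,
      is_synonymous = FALSE, fitness = doubles$fitness,
      stringsAsFactors = FALSE))

  nv <- nrow(variants)
  w <- stats::rgamma(nv, shape = config$dirichlet_concentration, rate = 1)
  w[1] <- w[1] * config$wt_weight
  w <- w / sum(w)
  input_count <- stats::rmultinom(1, config$depth, w)[, 1]
  sel_w <- w * variants$fitness^config$generations
  selected_count <- stats::rmultinom(1, config$depth, sel_w / sum(sel_w))[, 1]

  records <- data.frame(variant_id = variants$variant_id,
                        substitutions = variants$substitutions,
                        is_synonymous = variants$is_synonymous,
                        input_count = input_count,
                        selected_count = selected_count,
                        stringsAsFactors = FALSE)
  truth$variant_fitness <- stats::setNames(variants$fitness,
                                           variants$variant_id)
  truth$doubles <- doubles
  list(records = records, truth = truth)
}

#' Emit synthetic side tables (ASA, adjacency, ancestral posteriors)
#'
#' Buried positions receive fractional ASA drawn in [0, 0.1] and exposed
#' positions in (0.1, 0.95] (optional Gaussian noise, clipped to [0, 1]);
#' the adjacency table links each designated spatially proximal position
#' to a contact-site position; the ancestral posterior table is built to
#' exercise all three call outcomes (single, pair, ambiguous).
#'
#' @param config A \code{\link{simulation_config}}.
#' @param truth Truth bundle from \code{\link{simulate_homologs}} (used
#'   only to avoid reusing catalogue structure; may be NULL).
#' @return List with \code{asa}, \code{adjacency}, \code{posteriors} data
#'   frames and \code{truth}: buried/contact/proximal position sets and
#'   the expected call per (node, position).
#' @export
emit_side_tables <- function(config, truth = NULL) {
  set.seed(config$seed + 2L)
  L <- config$window_length
  buried <- sort(sample(seq_len(L), min(config$n_buried, L)))
  asa <- data.frame(position = seq_len(L),
                    fractional_asa = .runif_range(L, c(0.12, 0.95)))
  asa$fractional_asa[buried] <- stats::runif(length(buried), 0, 0.1)
  if (config$asa_noise > 0) {
    asa$fractional_asa <- pmin(1, pmax(0, asa$fractional_asa +
      stats::rnorm(L, 0, config$asa_noise)))
  }

  open_pos <- seq_len(L)
  contact <- sort(sample(open_pos, config$n_contact))
  # proximal positions: spatially linked to a contact residue but not its
  # immediate sequence neighbour
  far <- setdiff(open_pos,
                 unique(c(contact, contact - 1L, contact + 1L)))
  proximal <- sort(sample(far, min(config$n_proximal, length(far))))
  adjacency <- data.frame(position_i = proximal,
                          position_j = contact[1 + (seq_along(proximal) - 1) %%
                                                 length(contact)])

  aa <- .AA20
  kinds <- c("single", "pair", "ambiguous")
  rows <- list(); expected <- list()
  nodes <- sprintf("N%d", 1:4)
  positions <- sort(sample(seq_len(L), 9))
  i <- 0
  for (nd in nodes) for (p in positions[(i %% 3) * 3 + 1:3]) {
    kind <- kinds[(i %% 3) + 1]; i <- i + 1
    picks <- sample(aa, 3)
    probs <- switch(kind,
      single = stats::setNames(c(0.85, 0.10, 0.05), picks),
      pair = stats::setNames(c(0.45, 0.35, 0.20), picks),
      ambiguous = stats::setNames(c(0.40, 0.30, 0.30), picks))
    rows[[length(rows) + 1]] <- data.frame(node = nd, position = p,
                                           aa = names(probs),
                                           probability = as.numeric(probs),
                                           stringsAsFactors = FALSE)
    expected[[length(expected) + 1]] <- data.frame(node = nd, position = p,
                                                   call = kind,
                                                   stringsAsFactors = FALSE)
  }
  list(asa = asa, adjacency = adjacency,
       posteriors = do.call(rbind, rows),
       truth = list(buried_positions = buried,
                    contact_positions = contact,
                    proximal_positions = proximal,
                    expected_calls = do.call(rbind, expected)))
}

#' Simulate a large-scale two-hybrid selection with planted contact hits
#'
#' Synthetic stand-in for a large-scale two-hybrid interaction scan over
#' a contiguous domain segment: binding-disrupting substitutions are
#' planted at core contact positions, their immediate sequence
#' neighbours, spatially proximal positions (declared in the emitted
#' adjacency table) and a few unrelated positions, on a background of
#' near-neutral substitutions, then read out through the same
#' growth-and-sequencing machinery as the in vivo selection.
#'
#' @param seed Integer seed.
#' @param positions Integer vector of scanned residue positions.
#' @param core_positions Core contact positions carrying planted hits.
#' @param neighbor_positions,proximal_positions,other_positions Further
#'   planted-hit positions: immediate sequence neighbours of the core,
#'   spatially proximal residues, and unrelated residues.
#' @param hits_per_group Planted hit counts for the four groups, in the
#'   order core, neighbor, proximal, other.
#' @param n_background Near-neutral background substitutions.
#' @param n_synonymous,depth As in \code{\link{simulation_config}}.
#' @return List with \code{records} (count table; wild type \code{"WT"}),
#'   \code{core_positions}, \code{adjacency} (proximal-to-core links) and
#'   \code{truth} (planted hit labels per group).
#' @export
simulate_twohybrid_counts <- function(seed,
                                      positions = 131:197,
                                      core_positions = c(137, 138, 141, 145,
                                                         148, 181, 185, 186),
                                      neighbor_positions = c(136, 147, 149, 184),
                                      proximal_positions = c(150, 188, 189,
                                                             190, 192),
                                      other_positions = c(160, 165, 170),
                                      hits_per_group = c(22, 8, 11, 3),
                                      n_background = 380,
                                      n_synonymous = 150,
                                      depth = 1e6) {
  set.seed(seed)
  aa <- .AA20
  ref <- stats::setNames(sample(aa, length(positions), replace = TRUE),
                         positions)
  draw_subs <- function(pos_set, n) {
    # n substitutions spread over pos_set, distinct (position, alt)
    out <- character(0)
    while (length(out) < n) {
      p <- sample(rep(pos_set, length.out = max(n, length(pos_set))), 1)
      alt <- sample(setdiff(aa, ref[as.character(p)]), 1)
      lab <- substitution_label(p, ref[as.character(p)], alt)
      out <- union(out, lab)
    }
    out[seq_len(n)]
  }
  groups <- list(core = core_positions, neighbor = neighbor_positions,
                 proximal = proximal_positions, other = other_positions)
  planted <- mapply(draw_subs, groups, hits_per_group, SIMPLIFY = FALSE)
  hit_labels <- unlist(planted, use.names = FALSE)

  bg <- character(0)
  while (length(bg) < n_background) {
    p <- sample(positions, 1)
    alt <- sample(setdiff(aa, ref[as.character(p)]), 1)
    lab <- substitution_label(p, ref[as.character(p)], alt)
    if (!(lab %in% hit_labels)) bg <- union(bg, lab)
  }
  bg <- bg[seq_len(n_background)]

  labels <- c(hit_labels, bg)
  fitness <- c(stats::runif(length(hit_labels), 0.15, 0.42),
               stats::runif(length(bg), 0.85, 1.10))
  variants <- rbind(
    data.frame(variant_id = "WT", substitutions = "",
               is_synonymous = FALSE, fitness = 1, stringsAsFactors = FALSE),
    data.frame(variant_id = sprintf("syn%04d", seq_len(n_synonymous)),
               substitutions = "", is_synonymous = TRUE, fitness = 1,
               stringsAsFactors = FALSE),
    data.frame(variant_id = paste0("s_", labels), substitutions = labels,
               is_synonymous = FALSE, fitness = fitness,
               stringsAsFactors = FALSE))
  nv <- nrow(variants)
  w <- stats::rgamma(nv, shape = 50, rate = 1)
  w[1] <- w[1] * 50
  w <- w / sum(w)
  input_count <- stats::rmultinom(1, depth, w)[, 1]
  sel_w <- w * variants$fitness
  selected_count <- stats::rmultinom(1, depth, sel_w / sum(sel_w))[, 1]
  records <- data.frame(variant_id = variants$variant_id,
                        substitutions = variants$substitutions,
                        is_synonymous = variants$is_synonymous,
                        input_count = input_count,
                        selected_count = selected_count,
                        stringsAsFactors = FALSE)
  adjacency <- data.frame(
    position_i = proximal_positions,
    position_j = core_positions[1 + (seq_along(proximal_positions) - 1) %%
                                  length(core_positions)])
  list(records = records, core_positions = core_positions,
       adjacency = adjacency,
       truth = list(planted_hits = planted,
                    fitness = stats::setNames(variants$fitness,
                                              variants$variant_id)))
}

#' Write a full synthetic study to disk
#'
#' Emits every input file the pipeline consumes (count table, aligned
#' FASTA, ASA / adjacency / ancestral posterior tables) plus a
#' \code{truth/} directory with the planted ground truth, all under
#' \code{dir}. Filenames are prefixed \code{synthetic_} to mark the data
#' as simulator output.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hom <- simulate_homologs(config)
  sel <- simulate_selection_counts(config, hom$truth)
  side <- emit_side_tables(config, sel$truth)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  paths <- list(
    counts = file.path(dir, "synthetic_counts.tsv"),
    alignment = file.path(dir, "synthetic_alignment.fasta"),
    asa = file.path(dir, "synthetic_asa.tsv"),
    adjacency = file.path(dir, "synthetic_adjacency.tsv"),
    posteriors = file.path(dir, "synthetic_ancestral_posteriors.tsv"))
  write_count_table(sel$records, paths$counts)
  write_alignment_fasta(hom$alignment, paths$alignment)
  .write_tsv(side$asa, paths$asa)
  .write_tsv(side$adjacency, paths$adjacency)
  .write_tsv(side$posteriors, paths$posteriors)
  .write_tsv(sel$truth$catalogue, file.path(tdir, "catalogue.tsv"))
  if (!is.null(sel$truth$compensatory))
    .write_tsv(sel$truth$compensatory, file.path(tdir, "compensatory.tsv"))
  .write_tsv(sel$truth$doubles, file.path(tdir, "doubles.tsv"))
  invisible(paths)
}
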