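#' Specification of a synthetic floral-disparity dataset
#'
#' Bundles every knob of the generator. Defaults emulate the structure of a
#' large ordinal-scale floral dataset: 380 taxa scored for 36 mixed-type
#' characters with 13.4% missing and 2.2% polymorphic cells, a four-factor
#' ecological table (growth form, habitat, climate, region) with 3.6%
#' missing and 16.5% multi-valued cells, a planted two-block association
#' structure among factor categories, climate-linked trait dispersion (a
#' per-category symmetric Dirichlet parameter: higher dispersion means
#' higher within-category state entropy, hence higher disparity; dispersion
#' near 0 collapses a category onto a single state, driving its disparity
#' to 0), and species latitudinal ranges tied to climate so that tropical
#' taxa concentrate near the Equator.
#'
#' @param n_taxa number of taxa.
#' @param char_plan named integer vector: characters per kind.
#' @param n_states states per unordered / ordered character.
#' @param missing_frac,morph_polym_frac expected fractions of missing and
#'   polymorphic morphological cells.
#' @param factors named list of category vocabularies.
#' @param factor_missing_frac,factor_polym_frac expected fractions for the
#'   factor table.
#' @param group_factor factor whose categories drive trait dispersion and
#'   latitudinal ranges.
#' @param dispersion named numeric vector: Dirichlet dispersion per category
#'   of `group_factor`.
#' @param association_strength in \[0, 1\]: 0 draws all factors
#'   independently and uniformly, 1 draws them entirely from the planted
#'   two-block preferences.
#' @param block_prob probability that a taxon belongs to planted block 1
#'   (tropical forest trees of Africa/South America); the complement is
#'   block 2 (temperate/cold herbs and shrubs of open or wet habitats in
#'   North America/Eurasia).
#' @param lat_band named list: absolute-latitude band (degrees) of the
#'   range centre per `group_factor` category.
#' @param range_width latitudinal range width per species (degrees).
#' @param records_per_species expected occurrence records per species.
#' @param cont_sd_scale scale of the continuous-character spread
#'   (`sd = cont_sd_scale * sqrt(dispersion)`).
#' @param group_effect when `TRUE` (default) trait distributions are drawn
#'   per category of `group_factor`, planting real between-group structure;
#'   when `FALSE` one shared distribution (at the mean dispersion) is used
#'   for all taxa, so traits are independent of every grouping — the
#'   exchangeable null used for test calibration and for
#'   latitude-independent disparity.
#' @param seed mandatory integer seed.
#' @return validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_taxa = 380,
                       char_plan = c(binary = 18, unordered = 8,
                                     ordered = 6, continuous = 4),
                       n_states = c(unordered = 4, ordered = 4),
                       missing_frac = 0.134,
                       morph_polym_frac = 0.022,
                       factors = list(
                         growth_form = c("trees", "shrubs",
                                         "lianas and climbers",
                                         "herbs and aquatic herbs",
                                         "root parasites"),
                         habitat = c("forests", "open", "wet"),
                         climate = c("tropical", "arid", "temperate",
                                     "cold", "polar"),
                         region = c("North America", "Eurasia",
                                    "South America", "Africa",
                                    "Indo-Pacific", "Australia")),
                       factor_missing_frac = 0.036,
                       factor_polym_frac = 0.165,
                       group_factor = "climate",
                       dispersion = c(tropical = 3, arid = 0.4,
                                      temperate = 0.4, cold = 0.3,
                                      polar = 0.15),
                       association_strength = 0.8,
                       block_prob = 0.45,
                       lat_band = list(tropical = c(0, 23.5),
                                       arid = c(15, 35),
                                       temperate = c(30, 55),
                                       cold = c(45, 70),
                                       polar = c(60, 85)),
                       range_width = 20,
                       records_per_species = 20,
                       cont_sd_scale = 1,
                       group_effect = TRUE,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  fracs <- c(missing_frac, morph_polym_frac, factor_missing_frac,
             factor_polym_frac, association_strength, block_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (missing_frac + morph_polym_frac > 1 ||
      factor_missing_frac + factor_polym_frac > 1)
    stop("missing + polymorphic fractions exceed 1")
  stopifnot(n_taxa >= 2, all(char_plan >= 0), sum(char_plan) > 0)
  if (!group_factor %in% names(factors)) stop("unknown group_factor")
  gcats <- factors[[group_factor]]
  if (!all(gcats %in% names(dispersion)))
    stop("dispersion must name every category of ", group_factor)
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  if (!all(gcats %in% names(lat_band)))
    stop("lat_band must name every category of ", group_factor)
  if (morph_polym_frac > 0 && any(n_states < 2))
    stop("polymorphism needs characters with at least 2 states")
  structure(list(n_taxa = n_taxa, char_plan = char_plan, n_states = n_states,
                 missing_frac = missing_frac,
                 morph_polym_frac = morph_polym_frac, factors = factors,
                 factor_missing_frac = factor_missing_frac,
                 factor_polym_frac = factor_polym_frac,
                 group_factor = group_factor, dispersion = dispersion,
                 association_strength = association_strength,
                 block_prob = block_prob, lat_band = lat_band,
                 range_width = range_width,
                 records_per_species = records_per_species,
                 cont_sd_scale = cont_sd_scale,
                 group_effect = isTRUE(group_effect),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { # numerically degenerate: all mass on one state
    p <- numeric(length(alpha)); p[sample.int(length(alpha), 1L)] <- 1
    return(p)
  }
  g / sum(g)
}

## planted block preferences (weights over each factor's default categories;
## missing categories get weight 0). Block 1: tropical forest trees of
## Africa / South America. Block 2: temperate-to-polar herbs and shrubs of
## open / wet habitats in North America / Eurasia.
block_weights <- function(vocab, block) {
  pref <- if (block == 1L) list(
    growth_form = c(trees = 0.8, shrubs = 0.1, `lianas and climbers` = 0.1),
    habitat = c(forests = 1),
    climate = c(tropical = 1),
    region = c(Africa = 0.5, `South America` = 0.5))
  else list(
    growth_form = c(`herbs and aquatic herbs` = 0.5, shrubs = 0.5),
    habitat = c(open = 0.6, wet = 0.4),
    climate = c(temperate = 0.5, cold = 0.25, arid = 0.15, polar = 0.1),
    region = c(`North America` = 0.5, Eurasia = 0.5))
  out <- lapply(names(vocab), function(f) {
    w <- stats::setNames(rep(0, length(vocab[[f]])), vocab[[f]])
    pf <- pref[[f]]
    if (!is.null(pf)) {
      keep <- intersect(names(pf), names(w))
      w[keep] <- pf[keep]
    }
    if (sum(w) == 0) w[] <- 1   # factor absent from preferences: uniform
    w / sum(w)
  })
  names(out) <- names(vocab)
  out
}

gen_factor_core <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n_taxa
  taxa <- sprintf("sp%04d", seq_len(n))
  vocab <- spec$factors
  block <- 1L + (stats::runif(n) >= spec$block_prob)
  w1 <- block_weights(vocab, 1L); w2 <- block_weights(vocab, 2L)
  s <- spec$association_strength
  assigned <- matrix(NA_character_, n, length(vocab),
                     dimnames = list(taxa, names(vocab)))
  cat_prob <- function(i, f) {
    w <- if (block[i] == 1L) w1[[f]] else w2[[f]]
    s * w + (1 - s) / length(vocab[[f]])
  }
  for (f in names(vocab))
    for (i in seq_len(n))
      assigned[i, f] <- sample(vocab[[f]], 1L, prob = cat_prob(i, f))
  true_group <- assigned[, spec$group_factor]
  # inject missing and multi-membership; the extra category of a
  # multi-valued cell follows the taxon's own category distribution, so
  # co-memberships stay ecologically coherent (e.g. temperate + cold)
  # rather than pairing arbitrary categories
  cells <- matrix(vector("list", n * length(vocab)), n, length(vocab),
                  dimnames = list(taxa, names(vocab)))
  u <- matrix(stats::runif(n * length(vocab)), n)
  for (f in seq_along(vocab)) for (i in seq_len(n)) {
    cells[[i, f]] <- if (u[i, f] < spec$factor_missing_frac) {
      character(0)
    } else if (u[i, f] < spec$factor_missing_frac + spec$factor_polym_frac) {
      others <- setdiff(vocab[[f]], assigned[i, f])
      p <- cat_prob(i, names(vocab)[f])[match(others, vocab[[f]])]
      if (sum(p) == 0) p <- rep(1, length(others))
      extra <- sample(others, 1L, prob = p)
      c(assigned[i, f], extra)
    } else assigned[i, f]
  }
  list(ft = factor_table(cells, vocab, taxa), taxa = taxa,
       block = stats::setNames(block, taxa),
       true_group = stats::setNames(true_group, taxa))
}

gen_morph_core <- function(spec, true_group, taxa, seed) {
  set.seed(seed)
  n <- length(taxa)
  if (!spec$group_effect) {
    # exchangeable null: one shared trait distribution for all taxa
    true_group <- rep("__all__", n)
    names(true_group) <- taxa
    spec$dispersion <- c(`__all__` = mean(spec$dispersion))
  }
  plan <- spec$char_plan
  defs <- list(); kinds <- character(0)
  for (kind in names(plan)) kinds <- c(kinds, rep(kind, plan[[kind]]))
  for (k in seq_along(kinds)) {
    kind <- kinds[k]
    labs <- switch(kind,
      binary = c("0", "1"),
      unordered = paste0("s", seq_len(spec$n_states[["unordered"]])),
      ordered = as.character(seq_len(spec$n_states[["ordered"]]) - 1L),
      continuous = character())
    defs[[k]] <- character_definition(sprintf("c%02d", k), kind, labs)
  }
  groups <- unique(true_group)
  theta <- spec$dispersion
  # Hierarchical state model: each character has a shared baseline state
  # distribution p0; each group draws its own distribution around it,
  # p_g ~ Dirichlet(theta_g * S * p0). Within-group mismatch probability is
  # theta_g*S*(1 - sum(p0^2)) / (theta_g*S + 1): monotone in the dispersion
  # theta_g, collapsing to one state as theta_g -> 0 and approaching the
  # baseline entropy ceiling for large theta_g. Because all groups share
  # p0, between-group distances stay comparable to within-group ones
  # instead of dominating them.
  cells <- matrix(vector("list", n * length(defs)), n, length(defs))
  for (k in seq_along(defs)) {
    def <- defs[[k]]
    if (def$kind == "continuous") {
      mu0 <- stats::rnorm(1)
      mu <- stats::setNames(stats::rnorm(length(groups), mu0, 0.3), groups)
      for (i in seq_len(n)) {
        g <- true_group[i]
        sdg <- spec$cont_sd_scale * sqrt(theta[g])
        cells[[i, k]] <- stats::rnorm(1, mu[g], sdg)
      }
    } else {
      S <- length(def$state_labels)
      p0 <- rdirichlet1(rep(0.8, S))
      probs <- lapply(groups, function(g)
        rdirichlet1(theta[g] * S * p0 + 1e-3))
      names(probs) <- groups
      for (i in seq_len(n))
        cells[[i, k]] <- sample(def$state_labels, 1L,
                                prob = probs[[true_group[i]]])
    }
  }
  # inject missing / polymorphic cells uniformly
  u <- matrix(stats::runif(n * length(defs)), n)
  for (k in seq_along(defs)) for (i in seq_len(n)) {
    if (u[i, k] < spec$missing_frac) {
      cells[[i, k]] <- if (defs[[k]]$kind == "continuous") numeric(0)
                       else character(0)
    } else if (u[i, k] < spec$missing_frac + spec$morph_polym_frac) {
      def <- defs[[k]]
      if (def$kind == "continuous") {
        g <- true_group[i]
        cells[[i, k]] <- c(cells[[i, k]],
                           stats::rnorm(1, cells[[i, k]],
                                        spec$cont_sd_scale * sqrt(theta[g])))
      } else {
        extra <- sample(setdiff(def$state_labels, cells[[i, k]]), 1L)
        cells[[i, k]] <- c(cells[[i, k]], extra)
      }
    }
  }
  colnames(cells) <- vapply(defs, `[[`, character(1), "character_id")
  morph_matrix(cells, defs, taxa)
}

gen_occ_core <- function(spec, true_group, taxa, seed) {
  set.seed(seed)
  rows <- vector("list", length(taxa))
  for (i in seq_along(taxa)) {
    band <- spec$lat_band[[true_group[i]]]
    centre <- stats::runif(1, band[1], band[2]) * sample(c(-1, 1), 1L)
    nrec <- max(1L, stats::rpois(1, spec$records_per_species))
    lat <- stats::runif(nrec, centre - spec$range_width / 2,
                        centre + spec$range_width / 2)
    lat <- pmin(pmax(lat, -90), 90)
    rows[[i]] <- data.frame(species = taxa[i], latitude = lat,
                            longitude = stats::runif(nrec, -180, 180),
                            stringsAsFactors = FALSE)
  }
  occurrence_table(do.call(rbind, rows))
}

#' Generate a full synthetic dataset
#'
#' Draws, deterministically from `spec$seed`, a factor table with a planted
#' two-block association structure, a morphological matrix whose
#' within-category state entropy follows the per-category dispersion
#' parameter, and occurrence records whose latitudinal ranges follow the
#' taxon's climate category. The manifest records the generating truth
#' (block and group memberships, spec, seeds) for recovery tests.
#'
#' @param spec a [synth_spec()].
#' @return list with elements `m` ([morph_matrix()]), `ft`
#'   ([factor_table()]), `occ` ([occurrence_table()]) and `manifest`.
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  seeds <- spawn_seeds(spec$seed, 3L)
  fc <- gen_factor_core(spec, seeds[1])
  m <- gen_morph_core(spec, fc$true_group, fc$taxa, seeds[2])
  occ <- gen_occ_core(spec, fc$true_group, fc$taxa, seeds[3])
  list(m = m, ft = fc$ft, occ = occ,
       manifest = list(spec = unclass(spec), seeds = seeds,
                       block = fc$block, true_group = fc$true_group))
}

#' @rdname gen_dataset
#' @export
gen_morph_matrix <- function(spec) gen_dataset(spec)$m

#' @rdname gen_dataset
#' @export
gen_factor_table <- function(spec) gen_dataset(spec)$ft

#' @rdname gen_dataset
#' @export
gen_occurrences <- function(spec) gen_dataset(spec)$occ
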