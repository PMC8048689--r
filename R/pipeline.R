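#' Configuration of an end-to-end run
#'
#' @param input either a [synth_spec()] (data are simulated) or a named list
#'   of paths `list(matrix =, chardefs =, factors =, occurrences =)`.
#' @param stages character vector of stages to run, in any order; `"all"`
#'   expands to every stage. Stages: `simulate`, `disparity`, `test`,
#'   `associations`, `cluster-contrast`, `latitude`.
#' @param out_dir output directory (created if absent).
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_perm permutations per permutation test (desk scale 999;
#'   publication scale 9999).
#' @param n_resolutions polymorphism resolutions per aggregated test (desk
#'   scale 20; publication scale 100).
#' @param n_perm_contrast permutations for the cluster contrast
#'   (publication scale 99999).
#' @param alpha significance level for association edges.
#' @param pr_threshold minimal |Pearson residual| for an edge.
#' @param merges,exclusions category adjustments for contingency tables.
#' @param bin_width latitude bin width in degrees.
#' @param n_null_draws draws per bin for the richness-controlled null.
#' @param min_group_size minimal category size in permutation tests.
#' @param clusters optional list of two [cluster_spec()]s for the cluster
#'   contrast; when `NULL` the two largest positive components of the
#'   association network are used.
#' @param sep_poly,na_token file-format conventions for reading inputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(input, stages = "all", out_dir = "results",
                       seed = 1L, n_perm = 999, n_resolutions = 20,
                       n_perm_contrast = 9999, alpha = 0.05,
                       pr_threshold = 2, merges = character(),
                       exclusions = character(), bin_width = 10,
                       n_null_draws = 1000, min_group_size = 3L,
                       clusters = NULL, sep_poly = "/", na_token = "?") {
  all_stages <- c("simulate", "disparity", "test", "associations",
                  "cluster-contrast", "latitude")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(input = input, stages = stages, out_dir = out_dir,
                 seed = as.integer(seed), n_perm = n_perm,
                 n_resolutions = n_resolutions,
                 n_perm_contrast = n_perm_contrast, alpha = alpha,
                 pr_threshold = pr_threshold, merges = merges,
                 exclusions = exclusions, bin_width = bin_width,
                 n_null_draws = n_null_draws,
                 min_group_size = min_group_size, clusters = clusters,
                 sep_poly = sep_poly, na_token = na_token),
            class = "run_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## translate a set of (possibly merged) category labels back to per-factor
## admissible sets, undoing merges so cluster membership is tested against
## the original vocabulary
spec_from_categories <- function(ft, cats, merges = character()) {
  spec <- list()
  for (f in names(ft$factors)) {
    vocab <- ft$factors[[f]]
    lab <- vocab
    hit <- lab %in% names(merges)
    lab[hit] <- unname(merges[lab[hit]])
    adm <- vocab[lab %in% cats]
    if (length(adm)) spec[[f]] <- adm
  }
  if (length(spec) == 0L) stop("no factor categories matched the cluster")
  cluster_spec(spec, ft = ft)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order, writes every table as
#' TSV and every summary as JSON under `config$out_dir`, plus a manifest
#' with the configuration, derived seeds, package version and input
#' checksums. Reruns with the same configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 8L)
  names(seeds) <- c("simulate", "distance", "test", "associations",
                    "contrast", "latitude", "null", "spare")
  stages <- config$stages
  res <- list()
  cfg_public <- config[setdiff(names(config), "input")]
  if (!is.null(cfg_public$clusters))
    cfg_public$clusters <- lapply(cfg_public$clusters, unclass)
  manifest <- list(
    config = cfg_public,
    seeds = as.list(seeds),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("floradisp")))

  ## ---- inputs -----------------------------------------------------------
  simulated <- inherits(config$input, "synth_spec")
  if (simulated) {
    ds <- gen_dataset(config$input)
    m <- ds$m; ft <- ds$ft; occ <- ds$occ
    if ("simulate" %in% stages) {
      ind <- file.path(config$out_dir, "inputs")
      dir.create(ind, showWarnings = FALSE)
      write_morph_matrix(m, file.path(ind, "morph_matrix.tsv"),
                         file.path(ind, "chardefs.tsv"))
      write_factor_table(ft, file.path(ind, "factor_table.tsv"))
      write_occurrences(occ, file.path(ind, "occurrences.tsv"))
      write_json_report(
        list(spec = ds$manifest$spec,
             true_group = as.list(ds$manifest$true_group),
             block = as.list(ds$manifest$block)),
        file.path(ind, "truth.json"))
      manifest$input_files <- as.list(tools::md5sum(
        list.files(ind, full.names = TRUE)))
      res$simulate <- ds$manifest
    }
  } else {
    paths <- config$input
    need <- function(what, stage)
      if (is.null(paths[[what]]))
        stop("stage '", stage, "' needs input '", what, "'")
    m <- ft <- occ <- NULL
    if (any(stages != "latitude")) {
      need("matrix", stages[1]); need("chardefs", stages[1])
      m <- read_morph_matrix(paths$matrix, paths$chardefs,
                             sep_poly = config$sep_poly,
                             na_token = config$na_token)
    }
    if (any(c("disparity", "test", "associations", "cluster-contrast")
            %in% stages)) {
      need("factors", "test")
      ft <- read_factor_table(paths$factors, sep_poly = config$sep_poly,
                              na_token = config$na_token)
    }
    if ("latitude" %in% stages) {
      need("occurrences", "latitude")
      if (is.null(m)) {
        need("matrix", "latitude"); need("chardefs", "latitude")
        m <- read_morph_matrix(paths$matrix, paths$chardefs,
                               sep_poly = config$sep_poly,
                               na_token = config$na_token)
      }
      occ <- read_occurrences(paths$occurrences, taxa = m$taxa)
    }
    manifest$input_files <- as.list(tools::md5sum(unlist(paths)))
  }
  if (!is.null(m) && !is.null(ft) &&
      any(c("disparity", "test") %in% stages)) shared_taxa(m, ft)

  dm <- if (!is.null(m)) distance_matrix(m, seed = seeds["distance"]) else NULL

  ## ---- disparity --------------------------------------------------------
  if ("disparity" %in% stages) {
    tabs <- list()
    for (f in names(ft$factors)) {
      dt <- disparity_table(disparity_by_category(dm, ft, f))
      dt <- cbind(factor = f, dt)
      tabs[[f]] <- dt
    }
    all_tab <- do.call(rbind, tabs)
    write_tsv_report(all_tab, file.path(config$out_dir, "disparity.tsv"))
    res$disparity <- all_tab
  }

  ## ---- permutation tests ------------------------------------------------
  if ("test" %in% stages) {
    tseeds <- matrix(spawn_seeds(seeds["test"], 2L * length(ft$factors)),
                     ncol = 2L)
    anova_rows <- list(); posthoc_rows <- list()
    for (j in seq_along(ft$factors)) {
      f <- names(ft$factors)[j]
      a <- aggregate_over_resolutions(m, ft, f, "anova",
                                      n_perm = config$n_perm,
                                      n_resolutions = config$n_resolutions,
                                      base_seed = tseeds[j, 1],
                                      min_group_size = config$min_group_size)
      ph <- aggregate_over_resolutions(m, ft, f, "posthoc",
                                       n_perm = config$n_perm,
                                       n_resolutions = config$n_resolutions,
                                       base_seed = tseeds[j, 2],
                                       min_group_size = config$min_group_size)
      anova_rows[[f]] <- data.frame(factor = f, f_mean = a$stat_mean,
                                    f_sd = a$stat_sd, p_mean = a$p_mean,
                                    p_sd = a$p_sd,
                                    n_resolutions = a$n_resolutions)
      posthoc_rows[[f]] <- cbind(factor = f, ph$pairs)
      res$test[[f]] <- list(anova = a, posthoc = ph)
    }
    write_tsv_report(do.call(rbind, anova_rows),
                     file.path(config$out_dir, "tests_anova.tsv"))
    write_tsv_report(do.call(rbind, posthoc_rows),
                     file.path(config$out_dir, "tests_posthoc.tsv"))
  }

  ## ---- associations -----------------------------------------------------
  need_assoc <- any(c("associations", "cluster-contrast") %in% stages) &&
    is.null(config$clusters) || "associations" %in% stages
  edges <- NULL
  if (need_assoc) {
    scan <- association_scan(ft, merges = config$merges,
                             exclusions = config$exclusions)
    edges <- association_edges(scan, alpha = config$alpha,
                               pr_threshold = config$pr_threshold)
    if ("associations" %in% stages) {
      write_tsv_report(association_table(scan),
                       file.path(config$out_dir, "associations.tsv"))
      write_tsv_report(edges, file.path(config$out_dir, "association_edges.tsv"))
      D <- pr_profile_distance(scan)
      emb <- nmds_embed(D, seed = seeds["associations"], edges = edges)
      coords <- data.frame(category = rownames(emb$coordinates),
                           emb$coordinates, row.names = NULL)
      write_tsv_report(coords, file.path(config$out_dir, "nmds_coordinates.tsv"))
      write_json_report(list(stress = emb$stress, converged = emb$converged),
                        file.path(config$out_dir, "nmds_stress.json"))
      res$associations <- list(scan = scan, edges = edges, embedding = emb)
    }
  }

  ## ---- cluster contrast -------------------------------------------------
  if ("cluster-contrast" %in% stages) {
    specs <- config$clusters
    if (is.null(specs)) {
      comps <- network_clusters(edges)
      if (length(comps) < 2L)
        stop("stage 'cluster-contrast': fewer than 2 positive association ",
             "clusters found; supply config$clusters")
      specs <- lapply(comps[1:2], spec_from_categories, ft = ft,
                      merges = config$merges)
    }
    ma <- cluster_members(ft, specs[[1]])
    mb <- cluster_members(ft, specs[[2]])
    cc <- cluster_contrast(dm, ma, mb, n_perm = config$n_perm_contrast,
                           seed = seeds["contrast"])
    write_json_report(
      list(cluster_1 = unclass(specs[[1]]), cluster_2 = unclass(specs[[2]]),
           n_1 = cc$n_a, n_2 = cc$n_b,
           disparity_1 = cc$disparity_a$mean, sd_1 = cc$disparity_a$sd,
           disparity_2 = cc$disparity_b$mean, sd_2 = cc$disparity_b$sd,
           t_obs = cc$t_obs, p = cc$p, n_perm = cc$n_perm),
      file.path(config$out_dir, "cluster_contrast.json"))
    res$cluster_contrast <- cc
  }

  ## ---- latitudinal gradient ---------------------------------------------
  if ("latitude" %in% stages) {
    if (is.null(occ)) stop("stage 'latitude' needs occurrence records")
    prof <- bin_presence(occ, width = config$bin_width)
    prof <- profile_disparity(prof, dm)
    nulltab <- richness_controlled_null(prof, dm,
                                        n_draws = config$n_null_draws,
                                        seed = seeds["null"])
    tab <- cbind(prof$bins, nulltab[, c("null_mean", "q025", "q975", "p_emp")])
    write_tsv_report(tab, file.path(config$out_dir, "latitude_profile.tsv"))
    gr <- gradient_stats(prof, "richness")
    gd <- gradient_stats(prof, "disparity")
    gdr <- gradient_stats(prof, "disparity", covariate = "richness")
    write_json_report(
      list(richness_vs_latitude = unclass(gr),
           disparity_vs_latitude = unclass(gd),
           disparity_vs_richness = unclass(gdr)),
      file.path(config$out_dir, "latitude_stats.json"))
    res$latitude <- list(profile = prof, null = nulltab, richness = gr,
                         disparity = gd, disparity_vs_richness = gdr)
  }

  write_json_report(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(res)
}
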