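#' Run the full two-cohort comparison pipeline
#'
#' Orchestrates, per body site: Hill-number diversity comparisons
#' (community and phylum strata), shared-species tests (A1 and A2), PLE
#' heterogeneity-parameter comparisons (Type I and III), DAR fits with
#' MAD and a z comparison, co-occurrence network construction with
#' properties and MAO trio census, shared core/periphery tests (both
#' strategies), and shared-skeleton tests at the configured salience
#' thresholds. A failure in one stage is logged and does not abort the
#' others. Outputs one TSV per analysis plus a JSON manifest; runs are
#' byte-identical under a fixed config and seed.
#'
#' @param config named list or path to a YAML file with keys:
#'   `otu_table`, `metadata`, `taxonomy` (paths; or pass objects via the
#'   `...`-style keys `table_obj`, `metadata_obj`, `taxonomy_obj`),
#'   `sites` (optional; default all sites in the metadata),
#'   `group_field` (default `"sex"`), `q_values`, `n_perm`, `seed`,
#'   `min_total`, `fdr_alpha`, `salience_thresholds`, `output_dir`, and
#'   logical stage toggles `run_diversity`, `run_shared_species`,
#'   `run_ple`, `run_dar`, `run_network`, `run_cpn`, `run_hsn`.
#' @return Named list of per-site reports (invisibly if writing output).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(group_field = "sex", q_values = c(0, 1, 2, 3),
                   n_perm = 1000, seed = 1L, min_total = 80,
                   fdr_alpha = 0.001, salience_thresholds = c(0.25, 0.5),
                   n_orders = 20, output_dir = NULL,
                   run_diversity = TRUE, run_shared_species = TRUE,
                   run_ple = TRUE, run_dar = TRUE, run_network = TRUE,
                   run_cpn = TRUE, run_hsn = TRUE)
  cfg <- utils::modifyList(defaults, config)
  tab <- if (!is.null(cfg$table_obj)) cfg$table_obj
  else if (!is.null(cfg$otu_table)) read_otu_table(cfg$otu_table)
  else stop("config must provide `otu_table` (path) or `table_obj`")
  md <- if (!is.null(cfg$metadata_obj)) cfg$metadata_obj
  else if (!is.null(cfg$metadata)) read_sample_metadata(cfg$metadata)
  else stop("config must provide `metadata` (path) or `metadata_obj`")
  taxonomy <- if (!is.null(cfg$taxonomy_obj)) cfg$taxonomy_obj
  else if (!is.null(cfg$taxonomy)) read_taxonomy_map(cfg$taxonomy)
  else NULL
  sites <- cfg$sites
  if (is.null(sites)) sites <- sort(unique(md$body_site))
  reports <- lapply(sites, function(site)
    run_site(tab, md, taxonomy, site, cfg))
  names(reports) <- sites
  if (!is.null(cfg$output_dir)) write_reports(reports, cfg)
  invisible(reports)
}

stage <- function(report, name, expr) {
  report$stages[[name]] <- tryCatch(expr, error = function(e) {
    report$errors[[name]] <<- conditionMessage(e)
    NULL
  })
  report
}

run_site <- function(tab, md, taxonomy, site, cfg) {
  report <- list(site = site, parameters = cfg[c("q_values", "n_perm", "seed",
                                                 "min_total", "fdr_alpha",
                                                 "salience_thresholds")],
                 stages = list(), errors = list())
  halves <- split_by_group(tab, md, site, cfg$group_field)
  A <- halves[[1]]; B <- halves[[2]]
  report$groups <- names(halves)
  seed <- cfg$seed
  if (isTRUE(cfg$run_diversity)) {
    report <- stage(report, "diversity", {
      out <- compare_diversity(A, B, cfg$q_values)
      out$stratum <- "community"
      if (!is.null(taxonomy)) {
        phy <- phylum_of(taxonomy, otu_ids(tab))
        for (ph in setdiff(sort(unique(phy)), "Unknown")) {
          cmp <- tryCatch({
            x <- compare_diversity(A, B, cfg$q_values, taxa = phy, stratum = ph)
            x$stratum <- ph
            x
          }, error = function(e) NULL)
          if (!is.null(cmp)) out <- rbind(out, cmp)
        }
      }
      out
    })
  }
  if (isTRUE(cfg$run_shared_species)) {
    report <- stage(report, "shared_species", {
      list(A1 = shared_species_test(A, B, "A1", cfg$n_perm, child_seed(seed, 21)),
           A2 = shared_species_test(A, B, "A2", cfg$n_perm, child_seed(seed, 22)))
    })
  }
  if (isTRUE(cfg$run_ple)) {
    report <- stage(report, "ple", {
      lapply(stats::setNames(c("I", "III"), c("I", "III")), function(ty) {
        list(fitA = fit_power_law(ple_points(A, ty), ty),
             fitB = fit_power_law(ple_points(B, ty), ty),
             b_test = compare_scaling_param(A, B, ple_b_extractor(ty),
                                            cfg$n_perm,
                                            child_seed(seed, 30 + nchar(ty))))
      })
    })
  }
  if (isTRUE(cfg$run_dar)) {
    report <- stage(report, "dar", {
      lapply(stats::setNames(cfg$q_values, paste0("q", cfg$q_values)),
             function(q) {
               fa <- fit_dar(dar_curve(A, q, cfg$n_orders, child_seed(seed, 41)),
                             "PLEC", q)
               fb <- fit_dar(dar_curve(B, q, cfg$n_orders, child_seed(seed, 42)),
                             "PLEC", q)
               list(fitA = fa, fitB = fb,
                    madA = tryCatch(dar_mad(fa), error = function(e) NULL),
                    madB = tryCatch(dar_mad(fb), error = function(e) NULL),
                    z_test = compare_scaling_param(
                      A, B, dar_z_extractor(q, "PL", cfg$n_orders),
                      cfg$n_perm, child_seed(seed, 43)))
             })
    })
  }
  needs_net <- isTRUE(cfg$run_network) || isTRUE(cfg$run_cpn) || isTRUE(cfg$run_hsn)
  netA <- netB <- NULL
  if (needs_net) {
    report <- stage(report, "network", {
      netA <- build_scn(A, cfg$fdr_alpha, cfg$min_total)
      netB <- build_scn(B, cfg$fdr_alpha, cfg$min_total)
      stats_pairs <- permutated_pairs(
        A, B, n = cfg$n_perm, seed = child_seed(seed, 51),
        fdr_alpha = cfg$fdr_alpha, min_total = cfg$min_total,
        fun = function(a, b) c(nrow(a$edges), nrow(b$edges)))
      list(propertiesA = network_properties(netA),
           propertiesB = network_properties(netB),
           trioA = trio_census(netA, A), trioB = trio_census(netB, B),
           edge_count_test = compare_network_stat(
             nrow(netA$edges), nrow(netB$edges), stats_pairs))
    })
  }
  if (isTRUE(cfg$run_cpn) && !is.null(netA) && !is.null(netB)) {
    report <- stage(report, "cpn", {
      pa <- detect_core(netA, seed = child_seed(seed, 61))
      pb <- detect_core(netB, seed = child_seed(seed, 62))
      list(partitionA = pa, partitionB = pb,
           propertiesA = cpn_properties(netA, pa),
           propertiesB = cpn_properties(netB, pb),
           shared_core_observed = shared_core_observed(
             netA, netB, "core", cfg$n_perm, child_seed(seed, 63)),
           shared_core_permutated = shared_core_permutated(
             A, B, "core", cfg$n_perm, child_seed(seed, 64),
             cfg$fdr_alpha, cfg$min_total))
    })
  }
  if (isTRUE(cfg$run_hsn) && !is.null(netA) && !is.null(netB)) {
    report <- stage(report, "hsn", {
      lapply(stats::setNames(cfg$salience_thresholds,
                             paste0("s", cfg$salience_thresholds)),
             function(s) {
               res <- shared_skeleton_analysis(
                 A, B, s, cfg$n_perm, child_seed(seed, round(70 + 100 * s)),
                 cfg$fdr_alpha, cfg$min_total)
               list(test = res,
                    propertiesA = hsn_properties(res$skeletonA),
                    propertiesB = hsn_properties(res$skeletonB))
             })
    })
  }
  report
}

write_reports <- function(reports, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = cfg[c("q_values", "n_perm", "seed",
                                      "min_total", "fdr_alpha",
                                      "salience_thresholds", "group_field")],
                   sites = names(reports), files = list())
  for (site in names(reports)) {
    rep <- reports[[site]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", site)
    if (!is.null(rep$stages$diversity)) {
      f <- file.path(cfg$output_dir, paste0(safe, "_diversity.tsv"))
      utils::write.table(rep$stages$diversity, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$files[[paste0(site, ":diversity")]] <- basename(f)
    }
    summ <- summarize_tests(rep)
    if (nrow(summ)) {
      f <- file.path(cfg$output_dir, paste0(safe, "_tests.tsv"))
      utils::write.table(summ, f, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$files[[paste0(site, ":tests")]] <- basename(f)
    }
    if (length(rep$errors))
      manifest$errors[[site]] <- rep$errors
  }
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

# Flatten every perm_result in a site report into one tidy table.
summarize_tests <- function(rep) {
  rows <- list()
  add <- function(analysis, label, pr) {
    if (is.null(pr)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, test = label, observed = pr$observed,
      null_mean = pr$null_mean, p_value = pr$p_value, tail = pr$tail,
      n_perm = pr$n_perm, seed = pr$seed, stringsAsFactors = FALSE)
  }
  st <- rep$stages
  if (!is.null(st$shared_species)) {
    add("shared_species", "A1", st$shared_species$A1)
    add("shared_species", "A2", st$shared_species$A2)
  }
  if (!is.null(st$ple))
    for (ty in names(st$ple)) add("ple", paste0("b_type_", ty), st$ple[[ty]]$b_test)
  if (!is.null(st$dar))
    for (qn in names(st$dar)) add("dar", paste0("z_", qn), st$dar[[qn]]$z_test)
  if (!is.null(st$network))
    add("network", "edge_count", st$network$edge_count_test)
  if (!is.null(st$cpn)) {
    add("cpn", "shared_core_observed", st$cpn$shared_core_observed)
    add("cpn", "shared_core_permutated", st$cpn$shared_core_permutated)
  }
  if (!is.null(st$hsn))
    for (sn in names(st$hsn)) add("hsn", paste0("shared_skeleton_", sn),
                                  st$hsn[[sn]]$test)
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
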