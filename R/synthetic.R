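#' Specification for a synthetic two-cohort OTU dataset
#'
#' Defaults emulate the structure of a per-site two-sex 16S survey: two
#' cohorts of ~80 subjects each, a few hundred taxa with heavy-tailed
#' (lognormal) expected relative abundances, negative-binomial sequencing
#' depths, and optional cohort-specific taxa whose expected abundance in
#' the other cohort is zero.
#'
#' @param n_samples_a,n_samples_b samples (subjects) per cohort.
#' @param n_shared_taxa taxa present (in expectation) in both cohorts.
#' @param n_specific_a,n_specific_b taxa private to each cohort.
#' @param abund_meanlog,abund_sdlog lognormal parameters of expected
#'   relative abundances before normalisation (the sdlog of 1.5 yields the
#'   heavy rank-abundance tail typical of 16S OTU tables).
#' @param depth_mean,depth_size negative-binomial mean and size of the
#'   per-sample read depth.
#' @param taxon_overdispersion gamma shape controlling per-sample
#'   perturbation of the taxon proportions (each sample's composition is
#'   the cohort composition times independent Gamma(shape, shape) noise,
#'   renormalised - a Dirichlet-multinomial-style overdispersion).
#'   `Inf` (the default) disables it: every sample then draws from the
#'   exact cohort composition. Small values concentrate rare taxa into
#'   few samples, as real 16S data does.
#' @param phyla label set cycled over taxa for the taxonomy map.
#' @param group_labels the two cohort labels.
#' @param seed integer seed; the same spec and seed give bit-identical data.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples_a = 80, n_samples_b = 80,
                        n_shared_taxa = 300,
                        n_specific_a = 0, n_specific_b = 0,
                        abund_meanlog = 0, abund_sdlog = 1.5,
                        depth_mean = 5000, depth_size = 10,
                        taxon_overdispersion = Inf,
                        phyla = c("Actinobacteria", "Bacteroidetes",
                                  "Firmicutes", "Fusobacteria",
                                  "Proteobacteria"),
                        group_labels = c("M", "F"),
                        seed = 1L) {
  spec <- as.list(environment())
  if (n_samples_a < 1 || n_samples_b < 1) stop("need at least one sample per cohort")
  if (n_shared_taxa + n_specific_a < 1 || n_shared_taxa + n_specific_b < 1)
    stop("each cohort needs at least one taxon")
  if (length(group_labels) != 2 || anyDuplicated(group_labels))
    stop("`group_labels` must be two distinct labels")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic two-cohort OTU dataset
#'
#' Expected relative abundances are lognormal per taxon; shared taxa use
#' one common abundance across both cohorts (so with no specific taxa the
#' two cohorts are draws from a single distribution, the type-I setting of
#' the shared-species tests). Counts per sample are multinomial at a
#' negative-binomial depth.
#'
#' @param spec a [cohort_spec()].
#' @return List with elements `table` (counts-mode [otu_table()], cohort A
#'   samples first), `metadata` (data.frame: sample_id, subject_id, sex,
#'   body_site), `taxonomy` (named lineage vector), and `truth` (planted
#'   shared/specific taxon id lists plus the spec).
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n_taxa <- spec$n_shared_taxa + spec$n_specific_a + spec$n_specific_b
    ids <- sprintf("OTU%04d", seq_len(n_taxa))
    shared <- ids[seq_len(spec$n_shared_taxa)]
    specA <- ids[spec$n_shared_taxa + seq_len(spec$n_specific_a)]
    specB <- ids[spec$n_shared_taxa + spec$n_specific_a + seq_len(spec$n_specific_b)]
    base <- stats::rlnorm(n_taxa, spec$abund_meanlog, spec$abund_sdlog)
    pA <- base; pA[match(specB, ids)] <- 0
    pB <- base; pB[match(specA, ids)] <- 0
    pA <- pA / sum(pA); pB <- pB / sum(pB)
    od <- spec$taxon_overdispersion
    draw <- function(p, n, prefix) {
      depths <- pmax(1L, stats::rnbinom(n, mu = spec$depth_mean, size = spec$depth_size))
      m <- vapply(depths, function(d) {
        ps <- if (is.finite(od))
          p * stats::rgamma(n_taxa, shape = od, rate = od) else p
        stats::rmultinom(1, d, ps / sum(ps))[, 1]
      }, numeric(n_taxa))
      dimnames(m) <- list(ids, sprintf("%s%03d", prefix, seq_len(n)))
      m
    }
    mA <- draw(pA, spec$n_samples_a, paste0(spec$group_labels[1], "_s"))
    mB <- draw(pB, spec$n_samples_b, paste0(spec$group_labels[2], "_s"))
    tab <- otu_table(cbind(mA, mB), mode = "counts")
    md <- data.frame(
      sample_id = c(colnames(mA), colnames(mB)),
      subject_id = c(colnames(mA), colnames(mB)),
      sex = rep(spec$group_labels, c(ncol(mA), ncol(mB))),
      body_site = "synthetic_site",
      stringsAsFactors = FALSE)
    phy <- rep_len(spec$phyla, n_taxa)
    taxonomy <- stats::setNames(
      sprintf("k__Bacteria; p__%s; c__; o__; f__; g__; s__%s", phy, ids), ids)
    list(table = tab, metadata = md, taxonomy = taxonomy,
         truth = list(shared = shared, specific_a = specA, specific_b = specB,
                      p_a = stats::setNames(pA, ids), p_b = stats::setNames(pB, ids),
                      spec = spec))
  })
}

#' Specification for a cohort with planted correlation structure
#'
#' Taxa fall into three blocks: a core whose members load on one shared
#' latent factor (inducing high mutual rank correlation), periphery taxa
#' each tied to one core taxon, and independent background taxa. An
#' optional planted skeleton (a tree of taxon pairs) adds a chain of
#' dominant pairwise associations for salience-backbone recovery.
#'
#' @param n_taxa total taxa.
#' @param core_size number of core taxa (taxa 1..core_size).
#' @param periphery_size number of periphery taxa (attached round-robin to
#'   core taxa); the remainder is independent background.
#' @param strength_core,strength_cp latent loadings in \[0, 1\] for
#'   core-factor and core-periphery coupling.
#' @param skeleton_edges optional 2-column matrix of taxon indices forming
#'   a tree; these pairs get latent coupling `strength_skeleton`.
#' @param strength_skeleton loading for planted skeleton edges.
#' @param mu,size negative-binomial marginal mean and size of counts.
#' @param n_filler independent high-abundance taxa appended after the
#'   planted block. Relative-abundance closure divides every taxon by the
#'   sample total; when the correlated block carries most of the reads
#'   that division erases the planted rank structure, so the fillers keep
#'   the planted taxa a small fraction of each sample's depth (as the
#'   dominant taxa of a real community would).
#' @param filler_mu,filler_size negative-binomial parameters of the
#'   filler taxa (high mean, low dispersion).
#' @param seed integer seed.
#' @return Object of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_taxa = 24, core_size = 6,
                                 periphery_size = 12,
                                 strength_core = 0.9, strength_cp = 0.8,
                                 skeleton_edges = NULL,
                                 strength_skeleton = 0.95,
                                 mu = 200, size = 5,
                                 n_filler = 4, filler_mu = 10000,
                                 filler_size = 50, seed = 1L) {
  if (core_size >= n_taxa) stop("core_size must be smaller than n_taxa")
  if (core_size + periphery_size > n_taxa)
    stop("core_size + periphery_size exceeds n_taxa")
  if (any(c(strength_core, strength_cp, strength_skeleton) < 0) ||
      any(c(strength_core, strength_cp, strength_skeleton) > 1))
    stop("strengths must lie in [0, 1]")
  spec <- as.list(environment())
  class(spec) <- "planted_network_spec"
  spec
}

#' Generate a cohort OTU table with planted network structure
#'
#' Latent Gaussian variables carry the planted associations; each taxon's
#' latent values are mapped through the negative-binomial quantile
#' function (a rank-preserving transform), so Spearman correlation sees
#' the planted structure in the resulting counts.
#'
#' @param spec a [planted_network_spec()].
#' @param n_samples number of samples; below 30 a warning is issued
#'   (rank-correlation networks at stringent FDR have little power).
#' @param sample_prefix prefix for sample ids.
#' @return Counts-mode [otu_table()] with attribute `truth` (core,
#'   periphery, background taxon ids, planted skeleton pairs).
#' @export
generate_planted_network_cohort <- function(spec, n_samples,
                                            sample_prefix = "s") {
  stopifnot(inherits(spec, "planted_network_spec"))
  if (n_samples < 30)
    warning("n_samples < 30: co-occurrence networks at FDR 0.001 will have little power")
  with_seed(spec$seed, {
    n <- spec$n_taxa
    ids <- sprintf("OTU%04d", seq_len(n))
    core <- seq_len(spec$core_size)
    periph <- if (spec$periphery_size > 0)
      spec$core_size + seq_len(spec$periphery_size) else integer(0)
    z <- matrix(stats::rnorm(n * n_samples), n, n_samples)
    g <- stats::rnorm(n_samples)  # shared core factor
    sc <- spec$strength_core
    z[core, ] <- sc * rep(g, each = length(core)) +
      sqrt(1 - sc^2) * z[core, , drop = FALSE]
    if (length(periph)) {
      anchor <- rep_len(core, length(periph))
      scp <- spec$strength_cp
      z[periph, ] <- scp * z[anchor, , drop = FALSE] +
        sqrt(1 - scp^2) * matrix(stats::rnorm(length(periph) * n_samples),
                                 length(periph), n_samples)
    }
    if (!is.null(spec$skeleton_edges)) {
      se <- as.matrix(spec$skeleton_edges)
      ss <- spec$strength_skeleton
      for (k in seq_len(nrow(se))) {   # tree edges, parent listed first
        i <- se[k, 1]; j <- se[k, 2]
        z[j, ] <- ss * z[i, ] + sqrt(1 - ss^2) * stats::rnorm(n_samples)
      }
    }
    counts <- matrix(stats::qnbinom(stats::pnorm(z), mu = spec$mu,
                                    size = spec$size), n, n_samples)
    filler_ids <- character(0)
    if (spec$n_filler > 0) {
      filler_ids <- sprintf("OTU%04d", n + seq_len(spec$n_filler))
      fill <- matrix(stats::rnbinom(spec$n_filler * n_samples,
                                    mu = spec$filler_mu,
                                    size = spec$filler_size),
                     spec$n_filler, n_samples)
      counts <- rbind(counts, fill)
      ids <- c(ids, filler_ids)
    }
    dimnames(counts) <- list(ids, sprintf("%s%03d", sample_prefix,
                                          seq_len(n_samples)))
    tab <- otu_table(counts, mode = "counts")
    attr(tab, "truth") <- list(
      core = ids[core], periphery = ids[periph],
      background = ids[setdiff(seq_len(n), c(core, periph))],
      filler = filler_ids,
      skeleton_edges = if (is.null(spec$skeleton_edges)) NULL else
        cbind(ids[spec$skeleton_edges[, 1]], ids[spec$skeleton_edges[, 2]]),
      spec = spec)
    tab
  })
}

#' Generate variance-mean points from a power law
#'
#' Produces `(m, V)` pairs with `V = a * m^b` under multiplicative
#' lognormal noise of standard deviation `noise_sd` on the log scale;
#' `noise_sd = 0` gives exact points.
#'
#' @param a,b power-law parameters (`a > 0`).
#' @param n_points number of points (`>= 3`); `m` is drawn log-uniformly
#'   over two decades.
#' @param noise_sd standard deviation of the additive noise on `log(V)`.
#' @param seed integer seed.
#' @return data.frame with columns `m`, `V`.
#' @export
generate_power_law_points <- function(a, b, n_points = 80, noise_sd = 0.1,
                                      seed = 1L) {
  if (a <= 0) stop("`a` must be positive")
  if (n_points < 3) stop("need at least 3 points")
  with_seed(seed, {
    m <- 10^stats::runif(n_points, 0, 2)
    V <- a * m^b * exp(stats::rnorm(n_points, 0, noise_sd))
    data.frame(m = m, V = V)
  })
}
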