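#' Configuration for the multi-cohort synthetic study
#'
#' Defines the study conditions emulated by the generators: three brain-bank
#' cohorts with methylation subtypes planted on disjoint CpG signatures, one
#' cohort-specific cluster, covariate and batch structure, an EPIC-vs-450K
#' platform mask, negative-binomial expression with planted subtype DEGs and
#' CpG-linked genes, multinomial microglial-state cell counts with
#' state-specific marker shifts, and bounded morphology proportions with
#' group-specific variance.
#'
#' Additive structure is simulated on the logit scale so beta values stay
#' strictly inside (0,1) without clipping.
#'
#' @param seed Integer seed; all generators stream per-component seeds from it,
#'   so a fixed seed gives byte-identical output.
#' @param n_cohorts Number of cohorts (the last one is 450K-like).
#' @param samples_per_group Named counts per cohort for `Control`, `LOAD-S1`
#'   and `LOAD-S2` samples.
#' @param cohort_specific_n Extra LOAD samples planted as a cohort-specific
#'   cluster in cohort 1 only.
#' @param n_cpgs Number of CpGs per cohort before platform masking.
#' @param signature_sizes Named CpG counts for the disjoint signatures
#'   `S1`, `S2`, `sharedLOAD`, `cohortSpecific` and `NFT`.
#' @param effect_logit Named per-signature effect magnitudes on the logit
#'   scale (signs are drawn once per CpG and shared across cohorts).
#' @param covariate_effects Standard deviations of the per-CpG coefficients
#'   for age, sex, neuronal proportion and batch.
#' @param noise_sd Residual logit-scale noise for variable probes.
#' @param invariant_fraction Fraction of probes made near-constant
#'   (logit noise sd 0.02) to exercise the variability filter.
#' @param platform_mask_fraction Fraction of probes visible to the 450K-like
#'   cohort; at least half of every signature is always retained.
#' @param expression List: `n_genes`, `dispersion` (NB), `n_degs` per subtype,
#'   `fold_change`, `n_linked_pairs` (CpG-linked genes, monotone in LOAD-S2).
#' @param microglia List: `n_states`, `markers_per_state`,
#'   `n_background_genes`, `samples_per_group`, `total_cells_range`,
#'   `state_shift` (named logit shift of marker expression per state),
#'   `shift_group` (group receiving each shift), `rare_state_group` (group in
#'   which the last state is left with under 100 cells).
#' @param morphology List: `regions`, `n_per_group`, `groups`,
#'   `pam_mean_logit` and `pam_sd_logit` named per group.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cohorts = 3L,
                       samples_per_group = c(Control = 50L, `LOAD-S1` = 50L, `LOAD-S2` = 50L),
                       cohort_specific_n = 25L,
                       n_cpgs = 5000L,
                       signature_sizes = c(S1 = 150L, S2 = 150L, sharedLOAD = 100L,
                                           cohortSpecific = 150L, NFT = 150L),
                       effect_logit = c(S1 = 1.2, S2 = 1.2, sharedLOAD = 0.6,
                                        cohortSpecific = 1.4, NFT = 0.6),
                       covariate_effects = c(age = 0.01, sex = 0.15,
                                             cellprop = 0.8, batch = 0.25),
                       noise_sd = 0.3,
                       invariant_fraction = 0.2,
                       platform_mask_fraction = 0.6,
                       expression = list(),
                       microglia = list(),
                       morphology = list()) {
  expr_default <- list(n_genes = 2000L, dispersion = 0.1, n_degs = 50L,
                       fold_change = 2, n_linked_pairs = 20L, base_mean = 100)
  mg_default <- list(n_states = 4L, markers_per_state = 20L,
                     n_background_genes = 120L,
                     samples_per_group = c(Control = 20L, `LOAD-S1` = 20L, `LOAD-S2` = 20L),
                     total_cells_range = c(800L, 2000L),
                     state_shift = c(MG2 = 1),
                     shift_group = c(MG2 = "LOAD-S1"),
                     rare_state_group = "LOAD-S2")
  morph_default <- list(regions = c("IT", "MF", "VM", "PP"),
                        n_per_group = 20L,
                        groups = c("LOAD-S1", "LOAD-S2", "Unassigned", "AsymAD"),
                        pam_mean_logit = c(`LOAD-S1` = -0.8, `LOAD-S2` = -1.1,
                                           Unassigned = -1.1, AsymAD = -1.4),
                        pam_sd_logit = c(`LOAD-S1` = 0.8, `LOAD-S2` = 0.4,
                                         Unassigned = 0.4, AsymAD = 0.4))
  cfg <- list(seed = as.integer(seed), n_cohorts = as.integer(n_cohorts),
              samples_per_group = samples_per_group,
              cohort_specific_n = as.integer(cohort_specific_n),
              n_cpgs = as.integer(n_cpgs),
              signature_sizes = signature_sizes,
              effect_logit = effect_logit,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              invariant_fraction = invariant_fraction,
              platform_mask_fraction = platform_mask_fraction,
              expression = utils::modifyList(expr_default, expression),
              microglia = utils::modifyList(mg_default, microglia),
              morphology = utils::modifyList(morph_default, morphology))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cohorts >= 1, cfg$n_cpgs >= 1,
            all(cfg$samples_per_group > 0), cfg$cohort_specific_n >= 0,
            all(is.finite(cfg$effect_logit)), cfg$noise_sd > 0)
  if (sum(cfg$signature_sizes) > cfg$n_cpgs)
    stop("signature sizes (", sum(cfg$signature_sizes),
         ") exceed n_cpgs (", cfg$n_cpgs, ")")
  if (cfg$platform_mask_fraction <= 0 || cfg$platform_mask_fraction > 1)
    stop("platform_mask_fraction must lie in (0, 1]")
  invisible(cfg)
}

#' Generate the methylation part of a synthetic multi-cohort study
#'
#' Per-CpG logit(beta) is a shared baseline plus covariate, batch, cohort and
#' planted subtype terms plus Gaussian noise, mapped back through the inverse
#' logit. The `sharedLOAD` and `NFT` signatures shift every LOAD sample, the
#' `S1`/`S2` signatures only the corresponding subtype, and the
#' `cohortSpecific` signature an extra cluster present in cohort 1 only. The
#' last cohort exposes only a random probe subset (the 450K-like mask), with
#' at least half of every signature retained.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study` with elements `beta` (per-cohort
#'   probes x samples matrices), `samples` (per-cohort annotation frames with
#'   diagnosis, truth label and covariates), `probes` (coordinates, 0-based
#'   positions, and a 450K membership flag) and `truth` (signature CpG sets
#'   and the platform mask).
#' @export
generate_methylation_cohorts <- function(config) {
  validate_sim_config(config)
  g <- with_seed(stream_seed(config$seed, 1L), {
    n_cpgs <- config$n_cpgs
    probe_id <- sprintf("cg%06d", seq_len(n_cpgs))
    chr <- paste0("chr", sample(1:22, n_cpgs, replace = TRUE))
    pos <- sample.int(5e7, n_cpgs)
    invariant <- rbinom(n_cpgs, 1, config$invariant_fraction) == 1
    # signatures drawn from the variable probes, mutually disjoint
    pool <- which(!invariant)
    sizes <- config$signature_sizes
    if (sum(sizes) > length(pool))
      stop("signature sizes exceed the number of variable probes")
    picked <- sample(pool, sum(sizes))
    signatures <- split(probe_id[picked], rep(names(sizes), sizes))
    baseline <- rnorm(n_cpgs, sample(c(-2, 0, 2), n_cpgs, TRUE, prob = c(.4, .2, .4)), 0.5)
    probe_sd <- ifelse(invariant, 0.02, config$noise_sd)
    coefs <- sapply(config$covariate_effects, function(s) rnorm(n_cpgs, 0, s))
    effect <- numeric(n_cpgs)
    names(effect) <- probe_id
    for (sig in names(sizes)) {
      idx <- match(signatures[[sig]], probe_id)
      effect[idx] <- sample(c(-1, 1), length(idx), TRUE) * config$effect_logit[[sig]]
    }
    mask <- probe_id[sort(sample.int(n_cpgs, round(config$platform_mask_fraction * n_cpgs)))]
    for (sig in names(sizes)) {  # guarantee >= 50% of each signature on 450K
      miss <- setdiff(signatures[[sig]], mask)
      need <- ceiling(length(signatures[[sig]]) / 2) -
        (length(signatures[[sig]]) - length(miss))
      if (need > 0) mask <- c(mask, sample(miss, need))
    }
    mask <- probe_id[probe_id %in% mask]
    list(probe_id = probe_id, chr = chr, pos = pos, invariant = invariant,
         signatures = signatures, baseline = baseline, probe_sd = probe_sd,
         coefs = coefs, effect = effect, mask = mask)
  })

  beta <- samples <- vector("list", config$n_cohorts)
  sig_idx <- lapply(g$signatures, match, g$probe_id)
  for (co in seq_len(config$n_cohorts)) {
    res <- with_seed(stream_seed(config$seed, 10L + co), {
      spg <- config$samples_per_group
      truth <- rep(names(spg), spg)
      if (co == 1L && config$cohort_specific_n > 0)
        truth <- c(truth, rep("CohortSpecific", config$cohort_specific_n))
      n <- length(truth)
      ann <- data.frame(
        sample_id = sprintf("coh%d_s%03d", co, seq_len(n)),
        cohort = co,
        diagnosis = ifelse(truth == "Control", "Control", "LOAD"),
        truth = truth,
        age = round(rnorm(n, 75, 8), 1),
        sex = sample(c(0L, 1L), n, TRUE),
        prop_neuron = round(rbeta(n, 5, 5), 3),
        batch = sample(c("b1", "b2"), n, TRUE),
        stringsAsFactors = FALSE)
      cohort_offset <- rnorm(config$n_cpgs, 0, 0.1)
      lg <- matrix(g$baseline + cohort_offset, config$n_cpgs, n)
      lg <- lg + g$coefs[, "age"] %o% (ann$age - 75) +
        g$coefs[, "sex"] %o% as.numeric(ann$sex) +
        g$coefs[, "cellprop"] %o% (ann$prop_neuron - 0.5) +
        g$coefs[, "batch"] %o% as.numeric(ann$batch == "b2")
      is_load <- ann$diagnosis == "LOAD"
      add_effect <- function(lg, idx, who) {
        lg[idx, who] <- lg[idx, who] + g$effect[idx]
        lg
      }
      lg <- add_effect(lg, c(sig_idx$sharedLOAD, sig_idx$NFT), is_load)
      lg <- add_effect(lg, sig_idx$S1, ann$truth == "LOAD-S1")
      lg <- add_effect(lg, sig_idx$S2, ann$truth == "LOAD-S2")
      lg <- add_effect(lg, sig_idx$cohortSpecific, ann$truth == "CohortSpecific")
      lg <- lg + matrix(rnorm(length(lg), 0, g$probe_sd), config$n_cpgs, n)
      b <- expit(lg)
      dimnames(b) <- list(g$probe_id, ann$sample_id)
      list(beta = b, ann = ann)
    })
    beta[[co]] <- res$beta
    samples[[co]] <- res$ann
  }
  if (config$n_cohorts >= 2)  # last cohort is 450K-like
    beta[[config$n_cohorts]] <- beta[[config$n_cohorts]][g$mask, , drop = FALSE]
  probes <- data.frame(probe_id = g$probe_id, chr = g$chr, pos = g$pos,
                       on_450k = g$probe_id %in% g$mask,
                       invariant = g$invariant, stringsAsFactors = FALSE)
  structure(list(beta = beta, samples = samples, probes = probes,
                 truth = list(signatures = g$signatures, mask = g$mask,
                              effect = g$effect),
                 config = config),
            class = "synthetic_study")
}

#' Add synthetic bulk expression to a study
#'
#' Negative-binomial counts with log-normal library-size variation, planted
#' subtype DEGs at the configured fold change (random direction per gene), and
#' CpG-linked genes whose expected expression increases monotonically with the
#' linked planted CpG's beta value across LOAD-S2 samples.
#'
#' @param study A `synthetic_study` with the methylation part generated.
#' @param config The same [sim_config()].
#' @return The study with `expression` (per-cohort genes x samples counts),
#'   `genes` (TSS annotation, 0-based) and expression truth (`degs`,
#'   `linked_pairs`) added.
#' @export
generate_expression <- function(study, config = study$config) {
  ex <- config$expression
  s2_cpgs <- study$truth$signatures$S2
  if (ex$n_linked_pairs > min(ex$n_genes, length(s2_cpgs)))
    stop("n_linked_pairs exceeds min(n_genes, planted S2 CpGs)")
  glob <- with_seed(stream_seed(config$seed, 20L), {
    gene_id <- sprintf("g%05d", seq_len(ex$n_genes))
    chr <- paste0("chr", sample(1:22, ex$n_genes, replace = TRUE))
    tss <- sample.int(5e7, ex$n_genes)
    linked_gene <- sample(gene_id, ex$n_linked_pairs)
    linked_cpg <- sample(s2_cpgs, ex$n_linked_pairs)
    # place linked genes within the promoter window of their CpG
    li <- match(linked_gene, gene_id)
    ci <- match(linked_cpg, study$probes$probe_id)
    chr[li] <- study$probes$chr[ci]
    tss[li] <- pmax(1L, study$probes$pos[ci] + sample(-8000:8000, ex$n_linked_pairs))
    mu <- exp(rnorm(ex$n_genes, log(ex$base_mean), 1))
    subtypes <- c("LOAD-S1", "LOAD-S2")
    deg <- lapply(subtypes, function(s) sample(setdiff(gene_id, linked_gene), ex$n_degs))
    names(deg) <- subtypes
    deg_dir <- lapply(deg, function(gs) sample(c(-1, 1), length(gs), TRUE))
    list(gene_id = gene_id, chr = chr, tss = tss, mu = mu, deg = deg,
         deg_dir = deg_dir,
         linked = data.frame(cpg = linked_cpg, gene = linked_gene,
                             stringsAsFactors = FALSE))
  })
  counts <- vector("list", config$n_cohorts)
  for (co in seq_len(config$n_cohorts)) {
    ann <- study$samples[[co]]
    counts[[co]] <- with_seed(stream_seed(config$seed, 30L + co), {
      n <- nrow(ann)
      lib <- exp(rnorm(n, 0, 0.3))
      lmu <- matrix(log(glob$mu), ex$n_genes, n)
      for (s in names(glob$deg)) {
        gi <- match(glob$deg[[s]], glob$gene_id)
        who <- ann$truth == s
        if (any(who))
          lmu[gi, who] <- lmu[gi, who] + glob$deg_dir[[s]] * log(ex$fold_change)
      }
      # monotone beta -> expression link in LOAD-S2 samples
      who2 <- ann$truth == "LOAD-S2"
      present <- glob$linked$cpg %in% rownames(study$beta[[co]])
      if (any(who2) && any(present)) {
        lk <- glob$linked[present, , drop = FALSE]
        bcpg <- study$beta[[co]][lk$cpg, who2, drop = FALSE]
        gi <- match(lk$gene, glob$gene_id)
        z <- t(scale(t(logit(bcpg))))
        z[is.nan(z)] <- 0
        lmu[gi, who2] <- lmu[gi, who2] + 1.0 * z
      }
      mu <- sweep(exp(lmu), 2, lib, `*`)
      cts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / ex$dispersion),
                    ex$n_genes, n)
      dimnames(cts) <- list(glob$gene_id, ann$sample_id)
      cts
    })
  }
  study$expression <- counts
  study$genes <- data.frame(gene_id = glob$gene_id, chr = glob$chr,
                            tss = glob$tss, stringsAsFactors = FALSE)
  study$truth$degs <- glob$deg
  study$truth$deg_dir <- glob$deg_dir
  study$truth$linked_pairs <- glob$linked
  study
}

#' Generate synthetic microglial-state pseudobulk data
#'
#' Per-sample per-state cell counts are multinomial given a per-sample total;
#' per-state pseudobulk expression is log-normal, scaled by the state's cell
#' count, with each state's marker genes elevated within that state and the
#' configured marker shifts applied in the shifted group. The last state is
#' made rare (< 100 cells summed) in `rare_state_group` so the exclusion rule
#' is exercised.
#'
#' @param config A [sim_config()].
#' @param markers Optional named list of disjoint marker gene sets overriding
#'   the generated ones; overlapping sets are rejected.
#' @return A list of class `microglia_study`: `pseudobulk` (named list of
#'   genes x samples matrices), `cell_counts` (states x samples),
#'   `markers`, `samples` (sample/group frame) and `truth` (shift map).
#' @export
generate_microglia <- function(config, markers = NULL) {
  mg <- config$microglia
  stopifnot(mg$n_states >= 2)
  with_seed(stream_seed(config$seed, 40L), {
    states <- paste0("MG", seq_len(mg$n_states))
    n_marker_genes <- mg$n_states * mg$markers_per_state
    gene_id <- sprintf("mgg%04d", seq_len(n_marker_genes + mg$n_background_genes))
    if (is.null(markers)) {
      markers <- split(gene_id[seq_len(n_marker_genes)],
                       rep(states, each = mg$markers_per_state))
      markers <- markers[states]
    }
    all_m <- unlist(markers)
    if (anyDuplicated(all_m)) stop("marker sets must be disjoint")
    spg <- mg$samples_per_group
    samples <- data.frame(
      sample_id = sprintf("mg_s%03d", seq_len(sum(spg))),
      group = rep(names(spg), spg), stringsAsFactors = FALSE)
    n <- nrow(samples)
    # multinomial state composition; last state rare in rare_state_group
    base_prob <- rep(1, mg$n_states)
    totals <- sample(seq(mg$total_cells_range[1], mg$total_cells_range[2]), n, TRUE)
    cell_counts <- sapply(seq_len(n), function(i) {
      pr <- base_prob
      if (samples$group[i] == mg$rare_state_group) pr[mg$n_states] <- 0.005
      as.vector(rmultinom(1, totals[i], pr / sum(pr)))
    })
    dimnames(cell_counts) <- list(states, samples$sample_id)
    base_mu <- rnorm(length(gene_id), 5, 1)
    names(base_mu) <- gene_id
    pseudobulk <- lapply(states, function(st) {
      lmu <- matrix(base_mu, length(gene_id), n)
      lmu[match(markers[[st]], gene_id), ] <- lmu[match(markers[[st]], gene_id), ] + 2
      if (st %in% names(mg$state_shift)) {
        who <- samples$group == mg$shift_group[[st]]
        if (any(who)) {
          mi <- match(markers[[st]], gene_id)
          lmu[mi, who] <- lmu[mi, who] + mg$state_shift[[st]]
        }
      }
      lexpr <- lmu + matrix(rnorm(length(lmu), 0, 0.5), nrow(lmu), n)
      scale_fac <- cell_counts[st, ] / stats::median(cell_counts)
      cts <- round(sweep(2^lexpr, 2, pmax(scale_fac, 1e-3), `*`))
      dimnames(cts) <- list(gene_id, samples$sample_id)
      cts
    })
    names(pseudobulk) <- states
    structure(list(pseudobulk = pseudobulk, cell_counts = cell_counts,
                   markers = markers, samples = samples,
                   truth = list(state_shift = mg$state_shift,
                                shift_group = mg$shift_group)),
              class = "microglia_study")
  })
}

#' Generate a synthetic microglial morphology table
#'
#' Proportions of activated microglia (PAM) are drawn as inverse-logit
#' Gaussians per donor and region, so they respect [0,1] by construction;
#' per-group logit-scale standard deviations allow planting wider variance in
#' one subtype. A stage-3 burden measure is drawn alongside.
#'
#' @param config A [sim_config()].
#' @return Data frame with donor, region, group, `pam` and `stage3`.
#' @export
generate_morphology <- function(config) {
  mo <- config$morphology
  stopifnot(length(mo$regions) >= 1)
  with_seed(stream_seed(config$seed, 50L), {
    rows <- expand.grid(region = mo$regions, group = mo$groups,
                        donor_i = seq_len(mo$n_per_group),
                        stringsAsFactors = FALSE)
    rows$donor <- sprintf("d_%s_%02d", rows$group, rows$donor_i)
    rows$pam <- expit(rnorm(nrow(rows), mo$pam_mean_logit[rows$group],
                            mo$pam_sd_logit[rows$group]))
    rows$stage3 <- exp(rnorm(nrow(rows), log(50) + mo$pam_mean_logit[rows$group] / 2, 0.4))
    rows[, c("donor", "region", "group", "pam", "stage3")]
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators under the configuration's streamed seeds.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_study` with methylation, expression, microglia and
#'   morphology components plus the truth registry.
#' @export
simulate_study <- function(config) {
  study <- generate_methylation_cohorts(config)
  study <- generate_expression(study, config)
  study$microglia <- generate_microglia(config)
  study$morphology <- generate_morphology(config)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic multi-cohort methylation study\n")
  cat("  cohorts:", length(x$beta), "\n")
  for (co in seq_along(x$beta))
    cat(sprintf("  cohort %d: %d probes x %d samples\n", co,
                nrow(x$beta[[co]]), ncol(x$beta[[co]])))
  if (!is.null(x$expression))
    cat("  expression:", nrow(x$expression[[1]]), "genes\n")
  invisible(x)
}
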