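# Synthetic METex14-style cohort generator. Emulates the statistical
# structure the analysis pipeline assumes: four subtypes with planted
# pathway programs (MET-driven, FGFR-activated, immune-activated,
# bypass/multi-pathway), subtype-linked survival hazard (subtype A worst),
# per-sample METex14 VAF (subtype A highest), and clinical covariates with
# the subtype imbalances reported for the discovery cohort.

#' Synthetic cohort configuration
#'
#' Defaults describe the reference synthetic world used across the test
#' suite: 120 samples, 2000 genes, subtype proportions 0.30/0.15/0.19/0.36
#' (the discovery-cohort A-D proportions), 25 up-regulated and 25
#' down-regulated program genes per subtype in disjoint blocks, a 1.5 log2
#' mean shift against residual SD 1.0, exponential survival at baseline
#' hazard 0.02/month with subtype log hazard ratios (log 6.68, 0,
#' log 0.15, 0), uniform independent censoring calibrated to
#' `censor_rate`, and Beta-distributed METex14 VAF with subtype means
#' 0.30/0.15/0.12/0.18 at concentration 50.
#'
#' Programs are bidirectional (an up and a down block per subtype) so the
#' odds-ratio screening contract — 10 top and 10 bottom genes per subtype,
#' all subtype-specific — is satisfiable by construction.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param subtype_proportions 4 non-negative fractions summing to 1
#'   (subtypes A, B, C, D).
#' @param program_genes_per_subtype up-regulated genes planted per subtype.
#' @param program_down_genes_per_subtype down-regulated genes planted per
#'   subtype.
#' @param program_log2_effect mean log2 shift of program genes in their
#'   subtype.
#' @param noise_sd residual SD on the log2 scale.
#' @param baseline_log2_range range of per-gene baseline log2 means.
#' @param survival_baseline_hazard events per month at baseline.
#' @param survival_subtype_loghr 4 log hazard ratios (A largest by
#'   default).
#' @param censor_rate target fraction of censored samples.
#' @param vaf_means 4 per-subtype mean METex14 VAFs (A highest by default).
#' @param vaf_concentration Beta concentration for VAF draws.
#' @param seed integer seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 120,
                          n_genes = 2000,
                          subtype_proportions = c(A = 0.30, B = 0.15,
                                                  C = 0.19, D = 0.36),
                          program_genes_per_subtype = 25,
                          program_down_genes_per_subtype = 25,
                          program_log2_effect = 1.5,
                          noise_sd = 1.0,
                          baseline_log2_range = c(2, 8),
                          survival_baseline_hazard = 0.02,
                          survival_subtype_loghr = c(A = log(6.68), B = 0,
                                                     C = log(0.15), D = 0),
                          censor_rate = 0.6,
                          vaf_means = c(A = 0.30, B = 0.15,
                                        C = 0.12, D = 0.18),
                          vaf_concentration = 50,
                          seed = 1) {
  assert_scalar_count(n_samples, "n_samples")
  assert_scalar_count(n_genes, "n_genes")
  if (length(subtype_proportions) != 4 || any(subtype_proportions < 0))
    stop("subtype_proportions must be 4 non-negative fractions",
         call. = FALSE)
  if (abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must sum to 1", call. = FALSE)
  assert_scalar_count(program_genes_per_subtype, "program_genes_per_subtype")
  if (program_down_genes_per_subtype < 0)
    stop("program_down_genes_per_subtype must be >= 0", call. = FALSE)
  if (4 * (program_genes_per_subtype + program_down_genes_per_subtype) >
        n_genes)
    stop("program blocks exceed n_genes; blocks must be disjoint",
         call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (survival_baseline_hazard <= 0)
    stop("survival_baseline_hazard must be positive", call. = FALSE)
  if (length(survival_subtype_loghr) != 4)
    stop("survival_subtype_loghr must have 4 entries", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  if (length(vaf_means) != 4 || any(vaf_means <= 0) || any(vaf_means >= 1))
    stop("vaf_means must be 4 fractions in (0, 1)", call. = FALSE)
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              subtype_proportions = stats::setNames(subtype_proportions,
                                                    LETTERS[1:4]),
              program_genes_per_subtype =
                as.integer(program_genes_per_subtype),
              program_down_genes_per_subtype =
                as.integer(program_down_genes_per_subtype),
              program_log2_effect = program_log2_effect,
              noise_sd = noise_sd,
              baseline_log2_range = baseline_log2_range,
              survival_baseline_hazard = survival_baseline_hazard,
              survival_subtype_loghr = stats::setNames(survival_subtype_loghr,
                                                       LETTERS[1:4]),
              censor_rate = censor_rate,
              vaf_means = stats::setNames(vaf_means, LETTERS[1:4]),
              vaf_concentration = vaf_concentration,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Table-1-style per-subtype clinical sampling probabilities (A, B, C, D).
clinical_profiles <- function() {
  list(
    p_female = c(0.500, 0.684, 0.375, 0.644),
    age_mean = c(66.4, 62.6, 68.7, 63.2),
    age_sd = c(7.11, 8.57, 7.87, 8.02),
    stage = rbind(A = c(0.658, 0.211, 0.132),  # I / II / III
                  B = c(1, 0, 0),
                  C = c(1, 0, 0),
                  D = c(0.956, 0.022, 0.022)),
    t_stage = rbind(A = c(12, 18, 8), B = c(16, 2, 0),  # T1/T2/T3 counts
                    C = c(22, 0, 0), D = c(34, 7, 0)),
    n_stage = rbind(A = c(31, 3, 4), B = c(19, 0, 0),   # N0/N1/N2 counts
                    C = c(24, 0, 0), D = c(43, 1, 1)),
    p_pleural = c(15 / 38, 0, 1 / 24, 4 / 45))
}

#' Simulate a synthetic METex14-style cohort
#'
#' Expression is log-normal on the FPKM scale: per-gene baseline log2 means
#' plus the planted subtype program shifts plus Gaussian noise, then
#' `2^value`. Survival times follow an exponential proportional-hazards
#' model with independent uniform censoring whose upper bound is calibrated
#' so the expected censoring fraction matches `censor_rate`; observed times
#' are rounded up to whole months (producing the tied event times typical
#' of clinical follow-up). Each sample carries one METex14 variant record
#' with a Beta-distributed VAF around its subtype mean.
#'
#' @param config a [cohort_config].
#' @return a `synthetic_cohort` list: `expression` ([expression_matrix],
#'   FPKM state), `labels` (factor A-D), `clinical` (data.frame),
#'   `survival` (data.frame: `sample_id`, `time`, `event`), `variants`
#'   (data.frame incl. per-sample METex14 VAF), and `truth` (planted
#'   program genes, effects, seeds).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_samples
    g <- config$n_genes
    subtypes <- LETTERS[1:4]
    labels <- factor(sample(subtypes, n, replace = TRUE,
                            prob = config$subtype_proportions),
                     levels = subtypes)
    sample_ids <- sprintf("S%03d", seq_len(n))
    gene_ids <- sprintf("gene%04d", seq_len(g))

    n_up <- config$program_genes_per_subtype
    n_dn <- config$program_down_genes_per_subtype
    up_blocks <- lapply(0:3, function(s) seq_len(n_up) + s * n_up)
    dn_blocks <- if (n_dn > 0)
      lapply(0:3, function(s) 4 * n_up + seq_len(n_dn) + s * n_dn)
    else rep(list(integer(0)), 4)
    names(up_blocks) <- names(dn_blocks) <- subtypes

    base <- stats::runif(g, config$baseline_log2_range[1],
                         config$baseline_log2_range[2])
    shift <- matrix(0, g, 4, dimnames = list(gene_ids, subtypes))
    for (s in subtypes) {
      shift[up_blocks[[s]], s] <- config$program_log2_effect
      shift[dn_blocks[[s]], s] <- -config$program_log2_effect
    }
    log2x <- base + shift[, as.integer(labels)] +
      matrix(stats::rnorm(g * n, sd = config$noise_sd), g, n)
    dimnames(log2x) <- list(gene_ids, sample_ids)
    expr <- expression_matrix(2^log2x, "FPKM")

    prof <- clinical_profiles()
    si <- as.integer(labels)
    draw_cat <- function(weights, levels) {
      vapply(si, function(k) {
        w <- weights[k, ]
        sample(levels, 1, prob = if (sum(w) > 0) w else rep(1, length(w)))
      }, "")
    }
    clinical <- data.frame(
      sample_id = sample_ids,
      sex = ifelse(stats::runif(n) < prof$p_female[si], "Female", "Male"),
      age = round(stats::rnorm(n, prof$age_mean[si], prof$age_sd[si])),
      stage = draw_cat(prof$stage, c("I", "II", "III")),
      t_stage = draw_cat(prof$t_stage, c("T1", "T2", "T3")),
      n_stage = draw_cat(prof$n_stage, c("N0", "N1", "N2")),
      pleural_invasion = stats::runif(n) < prof$p_pleural[si],
      stringsAsFactors = FALSE)

    rates <- config$survival_baseline_hazard *
      exp(config$survival_subtype_loghr[si])
    t_event <- stats::rexp(n, rate = rates)
    if (config$censor_rate > 0) {
      u <- censor_bound(config)
      t_cens <- stats::runif(n, 0, u)
    } else t_cens <- rep(Inf, n)
    time <- ceiling(pmin(t_event, t_cens))
    time[time < 1] <- 1
    survival <- data.frame(sample_id = sample_ids,
                           time = as.numeric(time),
                           event = as.integer(t_event <= t_cens))

    a <- config$vaf_means[si] * config$vaf_concentration
    b <- (1 - config$vaf_means[si]) * config$vaf_concentration
    vaf <- stats::rbeta(n, a, b)
    depth <- 200L + stats::rpois(n, 300)
    alt <- stats::rbinom(n, depth, vaf)
    variants <- data.frame(sample_id = sample_ids, gene = "MET",
                           variant_class = "indel",
                           alt_read_count = alt,
                           vaf = vaf,
                           population_frequency = 0,
                           in_cds = TRUE, oncogenic = TRUE,
                           stringsAsFactors = FALSE)

    truth <- list(up_genes = lapply(up_blocks, function(i) gene_ids[i]),
                  down_genes = lapply(dn_blocks, function(i) gene_ids[i]),
                  program_log2_effect = config$program_log2_effect,
                  config = config)
    structure(list(expression = expr, labels = stats::setNames(labels,
                                                               sample_ids),
                   clinical = clinical, survival = survival,
                   variants = variants, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d genes; subtypes %s\n",
              ncol(x$expression), nrow(x$expression),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

# Upper bound of the uniform censoring window such that the expected
# censoring fraction over the subtype mixture equals censor_rate.
# For T ~ Exp(lambda), C ~ U(0, u): P(C < T) = (1 - exp(-lambda u)) /
# (lambda u).
censor_bound <- function(config) {
  lambda <- config$survival_baseline_hazard *
    exp(config$survival_subtype_loghr)
  pi <- config$subtype_proportions
  f <- function(u) {
    sum(pi * (1 - exp(-lambda * u)) / (lambda * u)) - config$censor_rate
  }
  stats::uniroot(f, lower = 1e-6, upper = 1e7, tol = 1e-9)$root
}

#' Simulate a variant table with planted filter truth
#'
#' Builds a record set in which each record is planted to either pass all
#' four variant filters or to fail exactly one designated criterion (while
#' passing the ones ordered before it), so the filter's kept count and
#' per-criterion rejection tally have an exact bookkeeping oracle.
#'
#' @param n_records number of records.
#' @param fail_fractions named fractions (`i`, `ii`, `iii`, `iv`) of
#'   records planted to fail each criterion; the remainder pass.
#' @param seed integer seed.
#' @return data.frame of variant records with a `planted` column
#'   (`"pass"`, `"i"`, ..., `"iv"`).
#' @export
simulate_variant_table <- function(n_records = 100,
                                   fail_fractions = c(i = 0.3, ii = 0.1,
                                                      iii = 0.1, iv = 0.1),
                                   seed = 1) {
  assert_scalar_count(n_records, "n_records")
  if (sum(fail_fractions) >= 1)
    stop("fail fractions must sum to < 1", call. = FALSE)
  with_local_seed(seed, {
    status <- sample(c(names(fail_fractions), "pass"), n_records,
                     replace = TRUE,
                     prob = c(fail_fractions, 1 - sum(fail_fractions)))
    n <- n_records
    pass_reads <- function(k) sample(5:200, k, replace = TRUE)
    pass_vaf <- function(k) stats::runif(k, 0.05, 0.6)
    rec <- data.frame(
      sample_id = sprintf("S%03d", sample.int(30, n, replace = TRUE)),
      gene = sample(c("TP53", "MET", "KRAS", "EGFR", "PIK3CA"), n,
                    replace = TRUE),
      variant_class = sample(c("SNV", "indel"), n, replace = TRUE,
                             prob = c(0.8, 0.2)),
      alt_read_count = pass_reads(n),
      vaf = pass_vaf(n),
      population_frequency = stats::runif(n, 0, 0.02),
      in_cds = TRUE, oncogenic = TRUE,
      planted = status, stringsAsFactors = FALSE)
    ii <- which(status == "i")
    # sub-threshold reads, sub-threshold VAF, or both
    mode <- sample(1:3, length(ii), replace = TRUE)
    rec$alt_read_count[ii[mode != 2]] <- sample(0:4, sum(mode != 2),
                                                replace = TRUE)
    rec$vaf[ii[mode != 1]] <- stats::runif(sum(mode != 1), 0, 0.049)
    jj <- which(status == "ii")
    rec$population_frequency[jj] <- stats::runif(length(jj), 0.021, 0.5)
    rec$in_cds[status == "iii"] <- FALSE
    rec$oncogenic[status == "iv"] <- FALSE
    rec
  })
}

#' Fixture gene-set collection for a synthetic cohort
#'
#' Builds the pathway collection the enrichment and clustering stages are
#' exercised on: one up-program and one down-program set per subtype (named
#' after the biological programs each subtype emulates) plus `n_random`
#' uninformative sets drawn from non-program genes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_random number of random background sets.
#' @param random_size genes per random set.
#' @param seed seed for the random sets.
#' @return a [gene_set_collection].
#' @export
fixture_gene_sets <- function(cohort, n_random = 4, random_size = 25,
                              seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  up_names <- c(A = "REACTOME_MET_ACTIVATES_PTK2_SIGNALING",
                B = "REACTOME_SIGNALING_BY_FGFR2",
                C = "IFNG_EFFECTOR_T_CELL_SIGNATURE",
                D = "KEGG_NOTCH_SIGNALING_PATHWAY")
  sets <- stats::setNames(cohort$truth$up_genes, up_names)
  dn <- cohort$truth$down_genes
  has_dn <- lengths(dn) > 0
  if (any(has_dn))
    sets <- c(sets, stats::setNames(dn[has_dn],
                                    paste0(up_names[has_dn], "_REPRESSED")))
  src <- rep("pathway", length(sets))
  if (n_random > 0) {
    planted <- unlist(c(cohort$truth$up_genes, cohort$truth$down_genes))
    pool <- setdiff(rownames(cohort$expression), planted)
    rnd <- with_local_seed(seed, lapply(seq_len(n_random), function(i)
      sample(pool, random_size)))
    names(rnd) <- sprintf("RANDOM_BACKGROUND_SET_%d", seq_len(n_random))
    sets <- c(sets, rnd)
    src <- c(src, rep("pathway", n_random))
  }
  gene_set_collection(sets, src)
}

#' Fixture TME / CAF marker panels for a synthetic cohort
#'
#' Small marker-mean signature panels keyed to the immune-activated
#' subtype's planted program (effector T cells, IFN-gamma) plus neutral CAF
#' marker sets, for exercising the marker-mean scorer.
#'
#' @param cohort a `synthetic_cohort`.
#' @param seed seed for the neutral sets.
#' @return a [gene_set_collection] with TME/CAF source labels.
#' @export
fixture_tme_sets <- function(cohort, seed = 1) {
  imm <- cohort$truth$up_genes$C
  planted <- unlist(c(cohort$truth$up_genes, cohort$truth$down_genes))
  pool <- setdiff(rownames(cohort$expression), planted)
  neutral <- with_local_seed(seed, list(
    MYCAF_MARKERS = sample(pool, 8),
    ICAF_MARKERS = sample(pool, 8)))
  gene_set_collection(
    c(list(EFFECTOR_T_CELLS = imm[seq_len(min(8, length(imm)))],
           IFNG_SIGNATURE = imm[seq_len(min(16, length(imm)))][-seq_len(8)]),
      neutral),
    source = c("TME-signature", "TME-signature",
               "CAF-signature", "CAF-signature"))
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `expression.tsv` (FPKM, genes x samples), `clinical.tsv`,
#' `survival.tsv`, `variants.tsv`, `truth.json`, and `gene_sets.gmt`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisible named vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             survival = file.path(dir, "survival.tsv"),
             variants = file.path(dir, "variants.tsv"),
             truth = file.path(dir, "truth.json"),
             gene_sets = file.path(dir, "gene_sets.gmt"))
  write_expression_tsv(cohort$expression, paths["expression"])
  cl <- cohort$clinical
  cl$subtype <- as.character(cohort$labels[cl$sample_id])
  utils::write.table(cl, paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$survival, paths["survival"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$variants, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_gmt(fixture_gene_sets(cohort), paths["gene_sets"])
  invisible(paths)
}
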