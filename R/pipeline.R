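# Orchestration: the discovery and validation pipelines, configuration
# round-tripping, and artifact writing. All interchange is plain
# TSV/GMT/JSON so runs are diffable; every random draw traces to the seeds
# recorded in the report.

#' Pipeline configuration
#'
#' @param paths named list/vector of input paths: `expression`,
#'   `gene_sets`, plus optional `clinical`, `survival`, `variants`, and
#'   `out_dir`.
#' @param enrichment list: `tau`, `normalize`.
#' @param clustering list: `k_range`, `n_resamples`, `subsample_fraction`,
#'   `threshold`.
#' @param classifier list: `n_top`, `n_bottom`, `cv_folds`, `iterations`,
#'   `run_loocv`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(paths,
                            enrichment = list(tau = 0.25, normalize = TRUE),
                            clustering = list(k_range = 2:6,
                                              n_resamples = 250,
                                              subsample_fraction = 0.8,
                                              threshold = 0.05),
                            classifier = list(n_top = 10, n_bottom = 10,
                                              cv_folds = 5, iterations = 20,
                                              run_loocv = FALSE),
                            seed = 1) {
  paths <- as.list(paths)
  if (is.null(paths$expression) || is.null(paths$gene_sets))
    stop("paths must include 'expression' and 'gene_sets'", call. = FALSE)
  if (is.null(paths$out_dir)) stop("paths must include 'out_dir'",
                                   call. = FALSE)
  structure(list(paths = paths, enrichment = enrichment,
                 clustering = clustering, classifier = classifier,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' Configurations round-trip unchanged, so a run can be reproduced from its
#' recorded config file alone.
#'
#' @param config a [pipeline_config].
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(paths = as.list(p$paths), enrichment = as.list(p$enrichment),
                  clustering = as.list(p$clustering),
                  classifier = as.list(p$classifier), seed = p$seed)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

check_inputs <- function(paths, required) {
  for (nm in required) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p))
      stop(sprintf("input '%s' missing or not found: %s", nm,
                   p %||% "<unset>"), call. = FALSE)
  }
}

stage <- function(name, runtimes, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  runtimes[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(value = res, runtimes = runtimes)
}

#' Run the discovery pipeline
#'
#' Executes normalize -> enrichment -> consensus clustering ->
#' characterization (differential expression, TME scores, variant filter,
#' cohort summary, survival association) -> classifier construction
#' (screen, lasso, refit) -> repeated cross-validation (and optional
#' LOOCV), writing every artifact into `config$paths$out_dir` along with a
#' report recording package version, config hash, seeds and per-stage
#' runtimes. Reruns with an identical config are bit-identical in all
#' serialized numeric outputs.
#'
#' @param config a [pipeline_config].
#' @return invisible list of in-memory results (`labels`, `consensus`,
#'   `model`, `cv`, `dge`, `survival`, ...).
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  check_inputs(config$paths, c("expression", "gene_sets"))
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rt <- list()

  s <- stage("load", rt, {
    expr <- read_expression_tsv(config$paths$expression, "FPKM")
    sets <- read_gmt(config$paths$gene_sets)
    clinical <- if (!is.null(config$paths$clinical) &&
                      file.exists(config$paths$clinical))
      utils::read.delim(config$paths$clinical, stringsAsFactors = FALSE)
    surv <- if (!is.null(config$paths$survival) &&
                  file.exists(config$paths$survival))
      utils::read.delim(config$paths$survival, stringsAsFactors = FALSE)
    variants <- if (!is.null(config$paths$variants) &&
                      file.exists(config$paths$variants))
      read_variant_tsv(config$paths$variants)
    list(expr = expr, sets = sets, clinical = clinical, surv = surv,
         variants = variants)
  }); rt <- s$runtimes; inp <- s$value

  s <- stage("normalize", rt, log_quantile_normalize(inp$expr))
  rt <- s$runtimes; norm <- s$value

  src <- attr(inp$sets, "source")
  pathway_sets <- inp$sets[src == "pathway"]
  marker_sets <- if (any(src != "pathway")) inp$sets[src != "pathway"]

  s <- stage("enrichment", rt,
             ssgsea_scores(norm, pathway_sets, tau = config$enrichment$tau,
                           normalize = config$enrichment$normalize))
  rt <- s$runtimes; scores <- s$value
  write_enrichment_tsv(scores, file.path(out, "enrichment.tsv"))

  s <- stage("consensus", rt,
             consensus_cluster(scores, k_range = config$clustering$k_range,
                               n_resamples = config$clustering$n_resamples,
                               subsample_fraction =
                                 config$clustering$subsample_fraction,
                               seed = child_seed(config$seed, 1),
                               threshold = config$clustering$threshold))
  rt <- s$runtimes; cons <- s$value
  labels <- cons$labels
  utils::write.table(data.frame(sample_id = names(labels),
                                subtype = as.character(labels)),
                     file.path(out, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(k_range = cons$k_range, stats = cons$stats,
                            selected_k = cons$selected_k,
                            resample_log = cons$resample_log),
                       file.path(out, "consensus_selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  s <- stage("characterize", rt, {
    dge <- lapply(levels(labels), function(cl) {
      a <- names(labels)[labels == cl]
      b <- setdiff(names(labels), a)
      if (length(a) < 2 || length(b) < 2) return(NULL)
      tab <- moderated_ttest(norm, a, b)
      utils::write.table(tab, file.path(out, sprintf("dge_%s.tsv", cl)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
    names(dge) <- levels(labels)
    tme <- if (!is.null(marker_sets)) {
      sc <- marker_signature_scores(norm, marker_sets)
      write_enrichment_tsv(sc, file.path(out, "tme_scores.tsv"))
      sc
    }
    summary_tab <- if (!is.null(inp$clinical)) {
      cl <- inp$clinical[match(names(labels), inp$clinical$sample_id), ,
                         drop = FALSE]
      st <- cohort_summary(cl[setdiff(names(cl), c("sample_id", "subtype"))],
                           labels)
      utils::write.table(st, file.path(out, "cohort_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      st
    }
    filt <- if (!is.null(inp$variants)) filter_variants(inp$variants)
    list(dge = dge, tme = tme, summary = summary_tab, variant_filter = filt)
  }); rt <- s$runtimes; charac <- s$value

  s <- stage("survival", rt, {
    if (is.null(inp$surv)) NULL else {
      sv <- inp$surv[match(names(labels), inp$surv$sample_id), ]
      lr <- logrank_test(sv$time, sv$event, labels)
      d <- data.frame(time = sv$time, event = sv$event,
                      subtype_A = as.integer(labels == "A"))
      cx <- cox_fit(d, "subtype_A", mode = "univariate")
      res <- list(logrank = lr, cox_subtype_A = cx,
                  km = lapply(split(seq_along(labels), labels), function(i)
                    km_estimate(sv$time[i], sv$event[i])["median"]))
      jsonlite::write_json(res, file.path(out, "survival.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res
    }
  }); rt <- s$runtimes; surv_res <- s$value

  s <- stage("classifier", rt, {
    model <- train_subtype_classifier(norm, labels,
                                      n_top = config$classifier$n_top,
                                      n_bottom = config$classifier$n_bottom,
                                      cv_folds = min(config$classifier$cv_folds,
                                                     min(table(labels))),
                                      seed = child_seed(config$seed, 2))
    write_classifier(model, file.path(out, "model.json"))
    model
  }); rt <- s$runtimes; model <- s$value

  s <- stage("cross_validation", rt, {
    cv <- repeated_cv(norm, labels, folds = config$classifier$cv_folds,
                      iterations = config$classifier$iterations,
                      seed = child_seed(config$seed, 3),
                      n_top = config$classifier$n_top,
                      n_bottom = config$classifier$n_bottom)
    lo <- if (isTRUE(config$classifier$run_loocv))
      loocv(norm, labels, seed = child_seed(config$seed, 4),
            n_top = config$classifier$n_top,
            n_bottom = config$classifier$n_bottom)
    jsonlite::write_json(list(mean_accuracy = cv$mean_accuracy,
                              sd_accuracy = cv$sd_accuracy,
                              per_iteration = cv$per_iteration,
                              loocv_concordance = lo$concordance %||% NULL),
                         file.path(out, "cv_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(cv = cv, loocv = lo)
  }); rt <- s$runtimes; cv_res <- s$value

  report <- list(package_version =
                   as.character(utils::packageVersion("metsubtype")),
                 config_hash = config_hash(config),
                 seed = config$seed,
                 selected_k = cons$selected_k,
                 n_samples = length(labels),
                 mean_cv_accuracy = cv_res$cv$mean_accuracy,
                 stage_runtimes_s = rt)
  jsonlite::write_json(report, file.path(out, "discovery_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(labels = labels, consensus = cons, model = model,
                 cv = cv_res$cv, loocv = cv_res$loocv, dge = charac$dge,
                 tme = charac$tme, summary = charac$summary,
                 variant_filter = charac$variant_filter,
                 survival = surv_res, enrichment = scores, report = report))
}

#' Run the validation pipeline
#'
#' Applies a serialized classifier to an independent cohort: predicts
#' subtypes, re-checks subtype-specific enrichment patterns on the
#' validation samples, and (when survival data are supplied) compares
#' predicted-subtype-A samples against the rest by log-rank test and Cox
#' fit — the MET-TKI-benefit style comparison.
#'
#' @param config a [pipeline_config] whose paths point at the validation
#'   cohort.
#' @param model_path path to a JSON model from [write_classifier()].
#' @return invisible list: `predictions`, `enrichment_by_subtype`,
#'   `survival`.
#' @export
run_validation <- function(config, model_path) {
  stopifnot(inherits(config, "pipeline_config"))
  check_inputs(config$paths, c("expression", "gene_sets"))
  if (!file.exists(model_path))
    stop("model file not found: ", model_path, call. = FALSE)
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  model <- read_classifier(model_path)
  expr <- read_expression_tsv(config$paths$expression, "FPKM")
  norm <- log_quantile_normalize(expr)
  pred <- predict_subtype(model, norm)
  utils::write.table(pred, file.path(out, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sets <- read_gmt(config$paths$gene_sets)
  src <- attr(sets, "source")
  scores <- ssgsea_scores(norm, sets[src == "pathway"],
                          tau = config$enrichment$tau,
                          normalize = config$enrichment$normalize)
  by_subtype <- vapply(model$classes, function(cl) {
    idx <- pred$label == cl
    if (!any(idx)) return(rep(NA_real_, nrow(scores)))
    rowMeans(scores[, idx, drop = FALSE])
  }, numeric(nrow(scores)))
  rownames(by_subtype) <- rownames(scores)

  surv_res <- NULL
  if (!is.null(config$paths$survival) &&
        file.exists(config$paths$survival)) {
    sv <- utils::read.delim(config$paths$survival, stringsAsFactors = FALSE)
    sv <- sv[match(pred$sample_id, sv$sample_id), ]
    grp <- factor(ifelse(pred$label == "A", "A", "other"),
                  levels = c("other", "A"))
    d <- data.frame(time = sv$time, event = sv$event,
                    predicted_A = as.integer(grp == "A"))
    surv_res <- list(logrank = logrank_test(sv$time, sv$event, grp),
                     cox_predicted_A = cox_fit(d, "predicted_A",
                                               mode = "univariate"))
  }

  report <- list(package_version =
                   as.character(utils::packageVersion("metsubtype")),
                 config_hash = config_hash(config),
                 model_version = model$version,
                 n_samples = nrow(pred),
                 predicted_counts = as.list(table(pred$label)))
  jsonlite::write_json(report, file.path(out, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(predictions = pred, enrichment_by_subtype = by_subtype,
                 survival = surv_res, report = report))
}
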