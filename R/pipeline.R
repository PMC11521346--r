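#' Save a trained model with provenance
#'
#' Writes a model directory: `provenance.json` (gene order, housekeeping set,
#' normalization flags, tap, head kind), the encoder weights (JSON), and the
#' head parameters (JSON for elastic net / neural; xgboost's own JSON format
#' for boosted heads) — everything needed to apply the model to a new tumor.
#'
#' @param model a [clcox()] or [clrisk()] fit.
#' @param dir output directory, created if needed.
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, c("clcox", "clrisk")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_cox <- inherits(model, "clcox")
  prov <- list(model_class = class(model)[1],
               genes = model$genes,
               cancer_type = model$cancer_type,
               tap = model$tap,
               housekeeping = if (is_cox) model$provenance$housekeeping,
               head_kind = if (is_cox) model$head$kind else model$classifier$kind,
               cutoff_years = if (!is_cox) model$cutoff_years,
               hr_median = if (is_cox) model$train$hr_median,
               seed = model$seed)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(model$encoder)) {
    enc <- model$encoder
    jsonlite::write_json(list(spec = unclass(enc$spec),
                              W = lapply(enc$net$W, as.numeric),  # column-major
                              b = enc$net$b,
                              input_dim = enc$net$input_dim,
                              widths = enc$net$widths),
                         file.path(dir, "encoder.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(enc$training_log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  }
  head <- if (is_cox) model$head else NULL
  kind <- prov$head_kind
  if (kind == "elastic_net") {
    jsonlite::write_json(list(beta = unname(head$params$beta),
                              alpha = head$params$alpha,
                              l1_ratio = head$params$l1_ratio,
                              baseline_t = if (!is.null(head$baseline))
                                stats::knots(head$baseline),
                              baseline_H0 = if (!is.null(head$baseline))
                                head$baseline(stats::knots(head$baseline))),
                         file.path(dir, "head.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else if (kind == "neural") {
    jsonlite::write_json(list(W = lapply(head$params$net$W, as.numeric),
                              b = head$params$net$b,
                              input_dim = head$params$net$input_dim,
                              widths = head$params$net$widths,
                              baseline_t = stats::knots(head$baseline),
                              baseline_H0 = head$baseline(stats::knots(head$baseline))),
                         file.path(dir, "head.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    booster <- if (is_cox) head$params$booster else model$classifier$fit$booster
    xgboost::xgb.save(booster, file.path(dir, "head.xgb.json"))
    if (is_cox)
      jsonlite::write_json(list(baseline_t = stats::knots(head$baseline),
                                baseline_H0 = head$baseline(stats::knots(head$baseline))),
                           file.path(dir, "head.json"), auto_unbox = TRUE,
                           digits = NA)
  }
  if (!is_cox && model$classifier$kind == "mlp") {
    net <- model$classifier$fit$net
    jsonlite::write_json(list(W = lapply(net$W, as.numeric), b = net$b,
                              input_dim = net$input_dim, widths = net$widths),
                         file.path(dir, "head.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

read_net_json <- function(obj) {
  widths <- as.integer(obj$widths)
  input_dim <- as.integer(obj$input_dim)
  dims <- c(input_dim, widths)
  W <- lapply(seq_along(widths), function(l)
    matrix(as.numeric(obj$W[[l]]), dims[l], dims[l + 1]))
  b <- lapply(obj$b, as.numeric)
  list(W = W, b = b, widths = widths, input_dim = input_dim)
}

#' Load a model saved by [save_model()]
#'
#' @param dir model directory.
#' @return A `"clcox"` or `"clrisk"` object sufficient for prediction
#'   (training history is not restored).
#' @export
load_model <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  enc <- NULL
  ep <- file.path(dir, "encoder.json")
  if (file.exists(ep)) {
    eo <- jsonlite::read_json(ep, simplifyVector = TRUE)
    net <- read_net_json(eo)
    spec <- eo$spec
    spec$layer_widths <- as.integer(spec$layer_widths)
    class(spec) <- "encoder_spec"
    enc <- structure(list(spec = spec, net = net, taps = mlp_taps(net),
                          training_log = NULL, stop_reason = "loaded",
                          best_epoch = NA, min_val_loss = NA,
                          input_genes = prov$genes),
                     class = "sc_encoder")
  }
  kind <- prov$head_kind
  if (prov$model_class == "clcox") {
    hp <- file.path(dir, "head.json")
    ho <- if (file.exists(hp)) jsonlite::read_json(hp, simplifyVector = TRUE)
    head <- if (kind == "elastic_net") {
      beta <- as.numeric(ho$beta)
      new_cox_head("elastic_net", list(beta = beta, alpha = ho$alpha,
                                       l1_ratio = ho$l1_ratio),
                   predict_fn = function(Fnew) drop(as.matrix(Fnew) %*% beta))
    } else if (kind == "neural") {
      net <- read_net_json(ho)
      new_cox_head("neural", list(net = net),
                   predict_fn = function(Fnew)
                     drop(mlp_forward(net, as.matrix(Fnew))[[3]]))
    } else {
      bst <- xgboost::xgb.load(file.path(dir, "head.xgb.json"))
      new_cox_head("gradient_boosted", list(booster = bst),
                   predict_fn = function(Fnew) {
                     M <- as.matrix(Fnew); dimnames(M) <- NULL
                     stats::predict(bst, xgboost::xgb.DMatrix(M, nthread = 1),
                                    outputmargin = TRUE)
                   })
    }
    if (!is.null(ho$baseline_t))
      head$baseline <- stats::stepfun(as.numeric(ho$baseline_t),
                                      c(0, as.numeric(ho$baseline_H0)),
                                      right = FALSE)
    head$feature_tap <- prov$tap
    structure(list(encoder = enc, head = head, tap = prov$tap,
                   genes = prov$genes, cancer_type = prov$cancer_type,
                   provenance = list(housekeeping = prov$housekeeping),
                   train = list(hr_median = prov$hr_median),
                   seed = prov$seed),
              class = "clcox")
  } else {
    fit <- if (kind == "mlp") {
      ho <- jsonlite::read_json(file.path(dir, "head.json"),
                                simplifyVector = TRUE)
      net <- read_net_json(ho)
      list(net = net, predict = function(Fnew)
        sigmoid(drop(mlp_forward(net, as.matrix(Fnew))[[length(net$W) + 1L]])))
    } else {
      bst <- xgboost::xgb.load(file.path(dir, "head.xgb.json"))
      list(booster = bst, predict = function(Fnew) {
        M <- as.matrix(Fnew); dimnames(M) <- NULL
        stats::predict(bst, xgboost::xgb.DMatrix(M, nthread = 1))
      })
    }
    clf <- structure(list(kind = kind, fit = fit), class = "risk_classifier")
    structure(list(encoder = enc, classifier = clf, tap = prov$tap,
                   genes = prov$genes, cutoff_years = prov$cutoff_years,
                   cancer_type = prov$cancer_type,
                   label_counts = c(high = NA, low = NA, excluded = NA),
                   seed = prov$seed),
              class = "clrisk")
  }
}

#' Apply a saved model to a new expression file
#'
#' Loads the model provenance, reads the expression table, re-applies the
#' recorded housekeeping normalization, aligns genes to the training order
#' (missing genes zero-filled, with a warning stating the count) and returns
#' per-sample predictions.
#'
#' @param model_dir a [save_model()] directory.
#' @param expression_path delimited expression file (genes x samples or
#'   samples x genes; orientation taken from the larger overlap with the
#'   model's genes).
#' @param normalized set TRUE if the file already holds normalized values.
#' @return data.frame of `sample_id` plus `risk_score` and `hazard_ratio`
#'   (clcox) or `risk_probability` (clrisk).
#' @export
apply_trained_model <- function(model_dir, expression_path, normalized = FALSE) {
  model <- load_model(model_dir)
  expr <- read_delim_auto(expression_path)
  row_labels <- as.character(expr[[1L]])
  M <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(M)) sc_stop("non-numeric expression values")
  genes_in_rows <- length(intersect(row_labels, model$genes)) >=
    length(intersect(colnames(M), model$genes))
  X <- if (genes_in_rows) {
    out <- t(M); colnames(out) <- row_labels; out
  } else M
  ids <- rownames(X) %||% sprintf("sample%03d", seq_len(nrow(X)))
  hk <- if (inherits(model, "clcox")) model$provenance$housekeeping$genes
  if (!normalized && !is.null(hk) && length(hk)) {
    ch <- cohort(X, time = rep(1, nrow(X)), event = rep(0L, nrow(X)),
                 sample_ids = ids, genes = colnames(X))
    ch <- normalize_housekeeping(ch, hk)
    X <- ch$X
  }
  tmp <- cohort(pmax(X, 0), time = rep(1, nrow(X)), event = rep(0L, nrow(X)),
                sample_ids = ids, genes = colnames(X))
  tmp <- align_genes(tmp, model$genes)
  if (inherits(model, "clcox")) {
    lp <- predict(model, tmp$X, type = "lp")
    data.frame(sample_id = ids, risk_score = lp, hazard_ratio = exp(lp))
  } else {
    data.frame(sample_id = ids,
               risk_probability = predict(model, tmp$X))
  }
}

# ---- YAML-driven end-to-end run ------------------------------------------

pipeline_schema <- list(
  seed = "integer",
  data = c("simulate", "expression", "clinical", "time_unit"),
  normalize = c("hk_genes"),
  pooling = c("group_name", "members", "target"),
  encoder = c("layer_widths", "learning_rate", "l2_weight", "batch_size",
              "max_epochs", "min_epochs", "patience", "tau", "normalize"),
  models = c("cox_heads", "classifier_kinds", "ablation", "tap",
             "classifier_tap"),
  evaluate = c("repeats", "train_frac", "cutoff_years", "target_size", "ibs",
               "logrank"),
  out = "path")

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(pipeline_schema))
  if (length(bad)) sc_stop("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (k in c("data", "normalize", "pooling", "encoder", "models", "evaluate")) {
    if (!is.null(cfg[[k]])) {
      extra <- setdiff(names(cfg[[k]]), pipeline_schema[[k]])
      if (k == "data" && !is.null(cfg$data$simulate)) extra <- setdiff(extra, character(0))
      if (length(extra)) sc_stop("unknown key(s) under '%s': %s", k,
                                 paste(extra, collapse = ", "))
    }
  }
  if (is.null(cfg$data)) sc_stop("config needs a 'data' section")
  invisible(TRUE)
}

#' Run the full pipeline from a YAML configuration
#'
#' One config drives: load or simulate a cohort, optional housekeeping
#' normalization, optional cross-cancer pooling, contrastive encoder
#' training, Cox and/or classifier heads with an optional no-encoder ablation
#' arm, and Monte-Carlo CV evaluation with rank-sum comparisons.
#'
#' @param config_path path to a YAML file; unknown keys are fatal.
#' @param dry_run if TRUE, print the resolved stage plan and return it
#'   without computing.
#' @return An `"eval_report"` (invisibly also written as JSON when the config
#'   sets `out`), or the stage plan if `dry_run`.
#' @export
run_pipeline <- function(config_path, dry_run = FALSE) {
  cfg <- yaml::read_yaml(config_path)
  if (!is.null(cfg$data$simulate)) {
    nm <- names(cfg$data$simulate)
    nm[nm %in% c("FALSE", "N")] <- "n"  # YAML 1.1 reads a bare `n` key as boolean
    names(cfg$data$simulate) <- nm
  }
  validate_config(cfg)
  seed <- cfg$seed %||% 1L
  plan <- list()
  if (!is.null(cfg$data$simulate)) {
    plan$data <- sprintf("simulate cohort (n=%s, p=%s)",
                         cfg$data$simulate$n %||% 300, cfg$data$simulate$p %||% 500)
  } else plan$data <- sprintf("load %s + %s", cfg$data$expression, cfg$data$clinical)
  if (!is.null(cfg$normalize)) plan$normalize <- "housekeeping normalization"
  if (!is.null(cfg$pooling)) plan$pooling <- sprintf("pool [%s] -> target %s",
                                                     paste(cfg$pooling$members, collapse = ","),
                                                     cfg$pooling$target)
  ev <- cfg$evaluate %||% list()
  plan$evaluate <- sprintf("%s-repeat Monte-Carlo CV", ev$repeats %||% 40)
  if (dry_run) {
    for (s in names(plan)) cat(sprintf("  %-10s %s\n", s, plan[[s]]))
    return(invisible(plan))
  }

  ch <- if (!is.null(cfg$data$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                cfg$data$simulate))
    simulate_cohort(sc)$cohort
  } else {
    load_cohort(cfg$data$expression, cfg$data$clinical,
                time_unit = cfg$data$time_unit %||% "days")
  }
  if (!is.null(cfg$normalize))
    ch <- normalize_housekeeping(ch, cfg$normalize$hk_genes)

  spec_args <- cfg$encoder %||% list()
  if (!is.null(spec_args$layer_widths))
    spec_args$layer_widths <- as.integer(unlist(spec_args$layer_widths))
  spec <- do.call(encoder_spec, utils::modifyList(
    list(max_epochs = 150, min_epochs = 30, patience = 60), spec_args))

  models <- cfg$models %||% list(cox_heads = "elastic_net", ablation = TRUE)
  variants <- list()
  for (hk in models$cox_heads %||% character(0)) {
    variants[[paste0("clcox_", hk)]] <-
      list(type = "cox", cl = TRUE, head = hk, encoder = spec,
           tap = models$tap %||% "hidden1",
           ibs = isTRUE(ev$ibs), logrank = isTRUE(ev$logrank),
           target_size = ev$target_size %||% 15)
    if (isTRUE(models$ablation))
      variants[[paste0("cox_", hk)]] <-
        list(type = "cox", cl = FALSE, head = hk,
             ibs = isTRUE(ev$ibs), logrank = isTRUE(ev$logrank))
  }
  for (ck in models$classifier_kinds %||% character(0)) {
    variants[[paste0("cl_", ck)]] <-
      list(type = "classifier", cl = TRUE, head = ck, encoder = spec,
           tap = models$classifier_tap %||% "output",
           cutoff_years = ev$cutoff_years %||% 3,
           target_size = ev$target_size %||% 15)
    if (isTRUE(models$ablation))
      variants[[paste0("raw_", ck)]] <-
        list(type = "classifier", cl = FALSE, head = ck,
             cutoff_years = ev$cutoff_years %||% 3)
  }
  if (length(variants) == 0L) sc_stop("config selects no models")

  report <- monte_carlo_cv(ch, variants, repeats = ev$repeats %||% 40,
                           train_frac = ev$train_frac %||% 0.8,
                           base_seed = seed)
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(aggregates = report$aggregates,
                              comparisons = report$comparisons),
                         file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(report$records, file.path(cfg$out, "records.csv"),
                     row.names = FALSE)
  }
  report
}
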