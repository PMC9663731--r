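#' Configure the full PRN pipeline
#'
#' Collects every stage's parameters into one reproducible configuration.
#' All stochastic stages derive their seed deterministically from the
#' global `seed` and the stage name, so one integer pins the whole run.
#' Either `input` + `schema` (a delimited table on disk) or `simulate`
#' (arguments for [registry_spec()]) must be supplied.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param input Optional path to a delimited input table.
#' @param schema Optional [registry_schema()] or path to a schema YAML.
#' @param simulate Optional list of [registry_spec()] arguments.
#' @param seed Global integer seed.
#' @param test_fraction Fraction of rows held out for evaluation.
#' @param impute `list(method = "zero"|"donors", strata =, m =)`.
#' @param mlp,anova,lasso,prn,evaluate Stage parameter lists; see
#'   [fit_mlp()], [decompose_logit()], [fit_response_lasso()],
#'   [retrain_prn()], [evaluate_scores()].
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `prn_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, schema = NULL,
                            simulate = NULL, seed = 1, test_fraction = 0.25,
                            impute = list(method = "zero"),
                            mlp = list(), anova = list(), lasso = list(),
                            prn = list(), evaluate = list(),
                            log_level = "info") {
  if (is.null(input) && is.null(simulate)) {
    abort("Provide either `input` (+ `schema`) or `simulate`.")
  }
  defaults <- list(
    mlp = list(hidden = c(4, 8, 16), l2 = 1e-3, validation_fraction = 0.2,
               max_epochs = 500, patience = 20, learning_rate = 0.05),
    anova = list(max_order = 2, n_grid = 101, max_pairs = Inf),
    lasso = list(nfolds = 10, rule = "min_cv"),
    prn = list(epochs = 500, learning_rate = 0.01, patience = 20,
               validation_fraction = 0.2),
    evaluate = list(groups = 10, level = 0.95)
  )
  structure(list(
    out_dir = out_dir, input = input, schema = schema, simulate = simulate,
    seed = seed, test_fraction = test_fraction, impute = impute,
    mlp = utils::modifyList(defaults$mlp, mlp),
    anova = utils::modifyList(defaults$anova, anova),
    lasso = utils::modifyList(defaults$lasso, lasso),
    prn = utils::modifyList(defaults$prn, prn),
    evaluate = utils::modifyList(defaults$evaluate, evaluate),
    log_level = log_level), class = "prn_config")
}

config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL; c2$log_level <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(c2, tmp, digits = NA, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' simulate/read, standardize and impute, fit the base MLP, decompose,
#' select by lasso, build and retrain the PRN, run the second selection
#' pass, evaluate on the held-out split, write per-patient explanations
#' and the nomogram. Every stage writes plain-text artifacts into
#' `out_dir` and a run manifest (`manifest.json`) with MD5 hashes; with
#' `resume = TRUE`, stages whose outputs already exist under an unchanged
#' configuration hash are loaded instead of recomputed.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip completed stages when their outputs exist.
#' @return Invisibly, a list with the fitted objects, the evaluation
#'   report and the artifact paths.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "prn_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  man_path <- file.path(config$out_dir, "manifest.json")
  old_manifest <- if (resume && file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  }
  if (!is.null(old_manifest) && !identical(unname(unlist(old_manifest$config_hash)), hash)) {
    old_manifest <- NULL  # config changed: recompute everything
  }
  say <- function(...) {
    if (!identical(config$log_level, "quiet")) message(sprintf(...))
  }
  pth <- function(...) file.path(config$out_dir, ...)
  done <- function(stage, files) {
    !is.null(old_manifest) && all(file.exists(pth(files))) &&
      stage %in% names(old_manifest$stages %||% list())
  }
  stages <- list()
  mark <- function(stages, stage, files) {
    stages[[stage]] <- list(files = files,
                            md5 = unname(tools::md5sum(pth(files))))
    stages
  }

  # -- data ------------------------------------------------------------
  if (done("data", "data.csv")) {
    say("[data] resumed")
    schema <- if (is.character(config$schema)) read_schema(config$schema) else config$schema
    data <- if (!is.null(schema)) read_registry(pth("data.csv"), schema) else {
      d <- readr::read_csv(pth("data.csv"), show_col_types = FALSE, progress = FALSE)
      attr(d, "outcome") <- "outcome"
      d
    }
  } else if (!is.null(config$simulate)) {
    spec <- do.call(registry_spec,
                    utils::modifyList(config$simulate,
                                      list(seed = derive_seed(config$seed, "simulate"))))
    data <- simulate_registry(spec)
    write_registry(data, pth("data.csv"))
    say("[data] simulated %d rows (prevalence %.3f)", nrow(data), mean(data$outcome))
  } else {
    schema <- if (is.character(config$schema)) read_schema(config$schema) else config$schema
    data <- read_registry(config$input, schema)
    write_registry(data, pth("data.csv"))
    say("[data] read %d rows from %s", nrow(data), config$input)
  }
  stages <- mark(stages, "data", "data.csv")

  # -- impute / split / standardize -------------------------------------
  if (identical(config$impute$method, "donors")) {
    data <- impute_donors(data, strata = config$impute$strata,
                          m = config$impute$m %||% 10,
                          seed = derive_seed(config$seed, "impute"))
    say("[impute] stacked %d donor-imputed copies", config$impute$m %||% 10)
  }
  withr::with_seed(derive_seed(config$seed, "split"), {
    n <- nrow(data)
    test_idx <- sample.int(n, max(1L, round(config$test_fraction * n)))
  })
  train <- data[-test_idx, , drop = FALSE]
  test <- data[test_idx, , drop = FALSE]
  for (a in c("schema", "outcome", "strata")) {
    attr(train, a) <- attr(data, a); attr(test, a) <- attr(data, a)
  }
  anchor <- compute_anchor(train)
  train_s <- impute_zero(standardize(train, anchor))
  test_s <- impute_zero(standardize(test, anchor))
  write_model(anchor, pth("anchor.json"))
  stages <- mark(stages, "anchor", "anchor.json")

  # -- fit --------------------------------------------------------------
  if (done("fit", "mlp.json")) {
    say("[fit] resumed")
    mlp <- read_model(pth("mlp.json"))
  } else {
    mlp <- do.call(fit_mlp, c(list(data = train_s,
                                   seed = derive_seed(config$seed, "fit")),
                              config$mlp))
    write_model(mlp, pth("mlp.json"))
    say("[fit] MLP with %d hidden units, val log-loss %.4f",
        mlp$hidden, min(mlp$history))
  }
  stages <- mark(stages, "fit", "mlp.json")

  # -- decompose --------------------------------------------------------
  decomp <- do.call(decompose_logit,
                    c(list(model = mlp, data = train_s), config$anova))
  write_model(decomp, pth("decomposition.json"))
  say("[decompose] %d candidate responses", length(decomp$responses))
  stages <- mark(stages, "decompose", "decomposition.json")

  # -- select -----------------------------------------------------------
  feats <- response_features(decomp, train_s)
  path <- fit_response_lasso(feats, train_s$outcome,
                             nfolds = config$lasso$nfolds,
                             seed = derive_seed(config$seed, "select"))
  gam <- select_responses(path, rule = config$lasso$rule)
  readr::write_csv(lasso_path_table(path), pth("lasso_path.csv"))
  jsonlite::write_json(
    list(rule = gam$rule, lambda = gam$lambda, intercept = gam$intercept,
         selected = gam$selected, beta = as.list(gam$beta)),
    pth("selection.json"), digits = NA, auto_unbox = TRUE)
  say("[select] %d responses selected: %s", length(gam$selected),
      paste(gam$selected, collapse = ", "))
  stages <- mark(stages, "select", c("lasso_path.csv", "selection.json"))

  # -- refine -----------------------------------------------------------
  prn0 <- build_prn(mlp, gam)
  prn <- retrain_prn(prn0, train_s,
                     seed = derive_seed(config$seed, "refine"),
                     epochs = config$prn$epochs,
                     learning_rate = config$prn$learning_rate,
                     patience = config$prn$patience,
                     validation_fraction = config$prn$validation_fraction)
  write_model(prn, pth("prn.json"))
  final <- prn_to_lasso(prn, train_s, nfolds = config$lasso$nfolds,
                        seed = derive_seed(config$seed, "refine_select"),
                        rule = config$lasso$rule,
                        n_grid = config$anova$n_grid)
  jsonlite::write_json(
    list(rule = final$rule, lambda = final$lambda, intercept = final$intercept,
         selected = final$selected, beta = as.list(final$beta)),
    pth("final_selection.json"), digits = NA, auto_unbox = TRUE)
  say("[refine] PRN retrained (%d epochs); final model keeps %d responses",
      prn$meta$stopped_epoch %||% 0L, length(final$selected))
  stages <- mark(stages, "refine", c("prn.json", "final_selection.json"))

  # -- evaluate ---------------------------------------------------------
  scored <- tibble(
    outcome = test_s$outcome,
    mlp = predict(mlp, test_s, type = "response"),
    prn_lasso = predict(final, response_features(final$decomp, test_s,
                                                 terms = final$selected)))
  report <- evaluate_scores(scored, c("prn_lasso", "mlp"),
                            groups = config$evaluate$groups,
                            level = config$evaluate$level)
  readr::write_csv(report, pth("evaluation.csv"))
  say("[evaluate] held-out AUROC: PRN-Lasso %.3f, MLP %.3f",
      report$auroc[1], report$auroc[2])
  stages <- mark(stages, "evaluate", "evaluation.csv")

  # -- explain + nomogram ----------------------------------------------
  expl <- explain(final, utils::head(test_s, 5))
  readr::write_csv(as_tibble(expl), pth("explanations.csv"))
  nomo <- export_nomogram(final, anchor = anchor)
  write_nomogram(nomo, pth("nomogram.csv"))
  stages <- mark(stages, "explain", "explanations.csv")
  stages <- mark(stages, "nomogram", "nomogram.csv")

  manifest <- list(package = "prnet",
                   version = as.character(utils::packageVersion("prnet")),
                   seed = config$seed, config_hash = hash, stages = stages)
  jsonlite::write_json(manifest, man_path, digits = NA, auto_unbox = TRUE)
  invisible(list(anchor = anchor, mlp = mlp, decomposition = decomp,
                 gam = gam, prn = prn, final = final, report = report,
                 nomogram = nomo, manifest = manifest,
                 out_dir = config$out_dir))
}
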