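# FNV-1a hash of a string, hex; used to fingerprint configs in output
# headers without any external dependency.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

config_hash <- function(config) {
  fnv1a(paste(deparse(config[sort(names(config))]), collapse = "\n"))
}

# TSV writer with '#' provenance header lines (version, seed, config
# hash) so every artifact records how it was produced.
write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# anchorsig ",
           as.character(utils::packageVersion("anchorsig"))),
    paste0("# seed: ", config$seed),
    paste0("# config: ", config_hash(config))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Configuration for the end-to-end pipeline
#'
#' @param out_dir output directory (created if absent).
#' @param expression,clinical,gene_sets input file paths (TSV expression,
#'   TSV clinical, GMT signature collection).  All three may be omitted
#'   when `simulate` is given, in which case the simulated cohort is
#'   written into `out_dir` and then read back, so every later stage
#'   runs from files.
#' @param simulate optional [simulation_config()].
#' @param anchors anchor gene identifiers (defaults to the simulation's
#'   anchors when simulating).
#' @param sam a [sam_params()].
#' @param alpha ssGSEA rank-weight exponent.
#' @param seed master seed; stage seeds are derived from it by salting
#'   with the stage name.
#' @param stages character vector of stages to run, a subset of
#'   `c("deg", "enrich", "associate", "survive")`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, expression = NULL, clinical = NULL,
                            gene_sets = NULL, simulate = NULL,
                            anchors = NULL, sam = sam_params(),
                            alpha = 0.75, seed = 1L,
                            stages = c("deg", "enrich", "associate",
                                       "survive")) {
  if (is.null(simulate)) {
    for (p in c(expression, clinical, gene_sets))
      if (!file.exists(p))
        abort(paste0("input path does not exist: ", p),
              "anchorsig_config_error")
    if (is.null(anchors))
      abort("anchors must be given when not simulating",
            "anchorsig_config_error")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, expression = expression,
                 clinical = clinical, gene_sets = gene_sets,
                 simulate = simulate, anchors = anchors, sam = sam,
                 alpha = alpha, seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes (optional) simulation, then DEG construction, enrichment
#' scoring, association profiling, and survival stratification, writing
#' each stage's tables under `out_dir/{deg,enrichment,association,
#' survival}` as TSV files with `#` provenance headers.  Stages
#' communicate only through these files, so any stage can be rerun from
#' a previous stage's output, and the same configuration always
#' reproduces byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of the paths written.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  out <- cfg$out_dir
  written <- character(0)
  for (d in c("", "deg", "enrichment", "association", "survival"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("[stage:%s] %s", name, conditionMessage(e)),
            "anchorsig_stage_error")
    })
  }

  expr_path <- cfg$expression; clin_path <- cfg$clinical
  gmt_path <- cfg$gene_sets
  if (!is.null(cfg$simulate)) {
    run_stage("simulate", function() {
      sim <- cfg$simulate
      sim$seed <- salt_seed(cfg$seed, "simulate_stage")
      cohort <- simulate_cohort(sim)
      write_expression(cohort$expression, file.path(out, "expression.tsv"))
      write_clinical(cohort$clinical, file.path(out, "clinical.tsv"))
      write_gmt(cohort$true_signatures, file.path(out, "signatures.gmt"))
      truth <- cohort$truth
      truth$anchor_activity <- NULL; truth$signature_activity <- NULL
      jsonlite::write_json(truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    })
    expr_path <- file.path(out, "expression.tsv")
    clin_path <- file.path(out, "clinical.tsv")
    gmt_path <- file.path(out, "signatures.gmt")
    if (is.null(cfg$anchors)) cfg$anchors <- cfg$simulate$anchors
    written <- c(written, expr_path, clin_path, gmt_path)
  }

  expr <- read_expression(expr_path, "tsv")
  clin <- read_clinical(clin_path)
  sets <- read_gmt(gmt_path)
  al <- align_samples(expr, clin)
  expr <- al$expression; clin <- al$clinical

  sam <- cfg$sam
  sam$seed <- salt_seed(cfg$seed, "deg_stage")

  deg <- NULL
  if ("deg" %in% cfg$stages) {
    deg <- run_stage("deg", function() {
      res <- build_deg_sets(expr, cfg$anchors, sam)
      for (anc in names(res$results)) {
        r <- res$results[[anc]]
        if (inherits(r, "deg_result"))
          write_stage_tsv(r$table,
                          file.path(out, "deg", paste0(anc, "_sam.tsv")), cfg)
      }
      write_gmt(res$sets, file.path(out, "deg", "deg_sets.gmt"))
      res
    })
    written <- c(written, file.path(out, "deg", "deg_sets.gmt"))
  }

  enr <- enr_deg <- NULL
  if ("enrich" %in% cfg$stages) {
    enr_all <- run_stage("enrich", function() {
      e_sig <- ssgsea_matrix(expr, sets, cfg$alpha)
      write_stage_tsv(
        data.frame(set = rownames(e_sig$es), e_sig$es, check.names = FALSE),
        file.path(out, "enrichment", "ssgsea_es.tsv"), cfg)
      write_stage_tsv(
        data.frame(set = rownames(e_sig$z), e_sig$z, check.names = FALSE),
        file.path(out, "enrichment", "ssgsea_z.tsv"), cfg)
      e_deg <- NULL
      if (!is.null(deg)) {
        e_deg <- ssgsea_matrix(expr, deg$sets, cfg$alpha)
        write_stage_tsv(
          data.frame(set = rownames(e_deg$z), e_deg$z, check.names = FALSE),
          file.path(out, "enrichment", "deg_ssgsea_z.tsv"), cfg)
      }
      list(sig = e_sig, deg = e_deg)
    })
    enr <- enr_all$sig; enr_deg <- enr_all$deg
    written <- c(written, file.path(out, "enrichment", "ssgsea_z.tsv"))
  }

  classification <- NULL
  if ("associate" %in% cfg$stages && !is.null(enr)) {
    classification <- run_stage("associate", function() {
      predictors <- lapply(cfg$anchors, function(a) expr[a, ])
      names(predictors) <- cfg$anchors
      if (!is.null(enr_deg))
        for (nm in rownames(enr_deg$z)) predictors[[nm]] <- enr_deg$z[nm, ]
      prof <- correlation_profile(predictors, enr, dataset_tag = "cohort")
      write_stage_tsv(
        data.frame(signature = rownames(prof), unclass(prof),
                   check.names = FALSE),
        file.path(out, "association", "correlation_profile.tsv"), cfg)
      cl <- classify_signatures(prof)
      write_stage_tsv(
        data.frame(signature = names(cl$sum_r), sum_r = unname(cl$sum_r),
                   class = ifelse(cl$sum_r > 0, "positive",
                                  ifelse(cl$sum_r < 0, "negative",
                                         "unassigned"))),
        file.path(out, "association", "classification.tsv"), cfg)
      cl
    })
    written <- c(written,
                 file.path(out, "association", "classification.tsv"))
  }

  if ("survive" %in% cfg$stages && !is.null(enr)) {
    run_stage("survive", function() {
      anchor <- cfg$anchors[1]
      strat_gene <- mean_sem_split(expr[anchor, ])
      sig <- if (!is.null(classification))
        names(which.max(abs(classification$sum_r))) else rownames(enr$z)[1]
      strat_sig <- mean_sem_split(enr$z[sig, ])
      two <- survival_by_stratification(strat_gene, clin)
      rows <- data.frame(
        analysis = "two_group", groups = paste0(anchor, ":high_vs_low"),
        n = sum(two$logrank$n), events = sum(two$logrank$observed),
        chi2 = two$logrank$chi2, df = two$logrank$df, p = two$logrank$p)
      four <- tryCatch(combined_survival(strat_gene, strat_sig, clin),
                       anchorsig_error = function(e) {
                         msg_log("four-group analysis skipped: ",
                                 conditionMessage(e)); NULL })
      if (!is.null(four)) {
        rows <- rbind(rows, data.frame(
          analysis = "four_group",
          groups = paste0(anchor, "x", sig),
          n = sum(four$overall$n), events = sum(four$overall$observed),
          chi2 = four$overall$chi2, df = four$overall$df,
          p = four$overall$p))
        km_tab <- do.call(rbind, lapply(names(four$km), function(g)
          cbind(group = g, four$km[[g]])))
        write_stage_tsv(km_tab,
                        file.path(out, "survival", "km_four_group.tsv"), cfg)
        write_stage_tsv(four$pairwise,
                        file.path(out, "survival", "pairwise_logrank.tsv"),
                        cfg)
      }
      km2 <- rbind(cbind(group = "high", two$km_high),
                   cbind(group = "low", two$km_low))
      write_stage_tsv(km2, file.path(out, "survival", "km_two_group.tsv"),
                      cfg)
      write_stage_tsv(rows, file.path(out, "survival", "logrank.tsv"), cfg)
    })
    written <- c(written, file.path(out, "survival", "logrank.tsv"))
  }
  invisible(written)
}
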