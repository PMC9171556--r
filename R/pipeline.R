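# Configuration-driven orchestration: generate -> fit -> compare -> report.

#' Format an estimate with its confidence interval
#'
#' Registry-table convention: two decimals, CI in parentheses with a
#' hyphen, e.g. \code{"4.51 (4.25-4.79)"}; missing CIs render as
#' \code{"NA"}.
#'
#' @param est Point estimate.
#' @param lower,upper CI limits (may be NA).
#' @return A character scalar.
#' @export
format_estimate_ci <- function(est, lower = NA, upper = NA) {
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  mapply(function(e, l, u) {
    if (!is.finite(e)) return("NA")
    if (!is.finite(l) || !is.finite(u)) return(fmt(e))
    paste0(fmt(e), " (", fmt(l), "-", fmt(u), ")")
  }, est, lower, upper, USE.NAMES = FALSE)
}

#' Format a proportion as a rounded percentage
#'
#' @param x Proportion in [0, 1] (NA allowed).
#' @return E.g. \code{"56\%"}; \code{"NA"} for missing.
#' @export
format_percent <- function(x) {
  ifelse(is.finite(x), paste0(round(100 * x), "%"), "NA")
}

# TSV with '# key: value' header comments (seed, preset, ...).
write_tsv_commented <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(paste0("# ", nm, ": ", meta[[nm]]), con)
  }
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a pairs or registry TSV written by the pipeline
#'
#' @param path File path; lines starting with \code{#} are header comments.
#' @return A data frame.
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Render fit and association results as aligned text tables
#'
#' Produces the model-grid report (one row per fitted model: components,
#' log-likelihood, AIC, LRT statistic and p against the full model) and,
#' when given, a hazard-ratio table, using the package's formatting
#' conventions (\code{\link{format_estimate_ci}},
#' \code{\link{format_percent}}).
#'
#' @param fits Named list of \code{\link{ace_fit}} objects (may be NULL).
#' @param comparisons Named list of \code{\link{compare_models}} results
#'   against the full model (may be NULL).
#' @param epi Optional data frame with columns \code{outcome},
#'   \code{hr}, \code{lower}, \code{upper}.
#' @return A list with \code{text} (character lines) and \code{tables}
#'   (list of data frames).
#' @export
render_tables <- function(fits = NULL, comparisons = NULL, epi = NULL) {
  if (is.null(fits) && is.null(epi)) {
    stop("render_tables needs at least one result object")
  }
  text <- character(0)
  tables <- list()
  if (!is.null(fits)) {
    grid <- data.frame(
      model = names(fits),
      loglik = vapply(fits, function(f) f$loglik, numeric(1)),
      AIC = vapply(fits, function(f) f$AIC, numeric(1)),
      npar = vapply(fits, function(f) f$npar, numeric(1)),
      lrt = NA_real_, df = NA_integer_, p_value = NA_real_,
      stringsAsFactors = FALSE
    )
    for (nm in names(comparisons)) {
      i <- match(nm, grid$model)
      grid$lrt[i] <- comparisons[[nm]]$lrt
      grid$df[i] <- comparisons[[nm]]$df
      grid$p_value[i] <- comparisons[[nm]]$p_value
    }
    tables$model_grid <- grid
    text <- c(text, "Model comparison (vs full ACE-ACE)",
              sprintf("%-6s %14s %14s %6s %10s %4s %10s", "model", "loglik",
                      "AIC", "npar", "LRT", "df", "p"),
              sprintf("%-6s %14.3f %14.3f %6d %10s %4s %10s",
                      grid$model, grid$loglik, grid$AIC, grid$npar,
                      ifelse(is.na(grid$lrt), "-", sprintf("%.3f", grid$lrt)),
                      ifelse(is.na(grid$df), "-", as.character(grid$df)),
                      ifelse(is.na(grid$p_value), "-",
                             sprintf("%.4g", grid$p_value))), "")
    for (nm in names(fits)) {
      de <- suppressWarnings(derived_estimates(fits[[nm]]))
      sh <- de$estimate[match(c("a2_1", "c2_1", "e2_1", "a2_2", "c2_2", "e2_2"),
                              de$quantity)]
      text <- c(text, sprintf(
        "%s: trait1 a2/c2/e2 = %s/%s/%s; trait2 = %s/%s/%s", nm,
        format_percent(sh[1]), format_percent(sh[2]), format_percent(sh[3]),
        format_percent(sh[4]), format_percent(sh[5]), format_percent(sh[6])))
    }
    text <- c(text, "")
  }
  if (!is.null(epi)) {
    if (nrow(epi) == 0L) stop("empty hazard-ratio table")
    tables$hazard_ratios <- epi
    text <- c(text, "Hazard ratios (exposure), adjusted for sex and birth year",
              sprintf("%-24s %s", "outcome", "HR (95% CI)"),
              sprintf("%-24s %s", epi$outcome,
                      format_estimate_ci(epi$hr, epi$lower, epi$upper)), "")
  }
  list(text = text, tables = tables)
}

#' Run the full generate/fit/report pipeline
#'
#' Validates the configuration, simulates the preset's cohort, runs the
#' requested analyses and writes all reports plus a run manifest.  Re-runs
#' with the same configuration reproduce all numeric outputs bit
#' identically.
#'
#' @param config A list (or path to a YAML file) with fields
#'   \code{preset}, \code{analyses} (subset of \code{"genetic"},
#'   \code{"phenotypic"}), \code{out_dir}, \code{seed} (integer),
#'   \code{replicates} (default 1).
#' @return Invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  stopifnot(is.list(cfg))
  if (is.null(cfg$replicates)) cfg$replicates <- 1L
  if (is.null(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config$seed must be an integer")
  }
  if (cfg$replicates < 1) stop("config$replicates must be >= 1")
  known <- c("genetic", "phenotypic")
  if (is.null(cfg$analyses) || !all(cfg$analyses %in% known)) {
    stop("config$analyses must be a subset of: ", paste(known, collapse = ", "))
  }
  preset <- load_preset(cfg$preset)   # validates the name before compute
  if (preset$kind == "registry" && "genetic" %in% cfg$analyses) {
    stop("genetic analysis requires a pair preset, not a registry preset")
  }
  if (preset$kind == "item_panel") {
    stop("the item-panel preset has no pipeline analyses")
  }
  if (!is.null(cfg$counts)) preset$counts <- unlist(cfg$counts)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  status <- list()
  meta <- list(preset = cfg$preset, seed = cfg$seed)

  if (preset$kind %in% c("pairs_continuous", "pairs_binary")) {
    pairs <- simulate_kin_pairs(
      preset$components, preset$counts,
      thresholds = preset$thresholds, covariate_effects = preset$covariates,
      seed = cfg$seed)
    write_tsv_commented(pairs, file.path(cfg$out_dir, "pairs.tsv"), meta)
    status$simulate <- "ok"

    if ("genetic" %in% cfg$analyses) {
      ladder <- fit_ace_ladder(pairs, ref_year = preset$covariates$ref_year)
      rep_rows <- NULL
      if (cfg$replicates > 1L) {
        rep_rows <- lapply(seq_len(cfg$replicates), function(r) {
          p_r <- simulate_kin_pairs(
            preset$components, preset$counts, thresholds = preset$thresholds,
            covariate_effects = preset$covariates,
            seed = derive_seed(cfg$seed, paste0("replicate-", r)))
          f <- fit_ace(p_r, ace_model_spec(c("A", "E")),
                       ref_year = preset$covariates$ref_year)
          de <- suppressWarnings(derived_estimates(f))
          cbind(replicate = r, de)
        })
        write_tsv_commented(do.call(rbind, rep_rows),
                            file.path(cfg$out_dir, "replicates.tsv"), meta)
      }
      rendered <- render_tables(ladder$fits, ladder$comparisons)
      writeLines(rendered$text, file.path(cfg$out_dir, "fit_report.txt"))
      utils::write.table(rendered$tables$model_grid,
                         file.path(cfg$out_dir, "fit_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      best_fit <- ladder$fits[[ladder$best]]
      report <- list(
        best_model = ladder$best,
        models = lapply(ladder$fits, function(f) list(
          components = f$spec$components, loglik = f$loglik, AIC = f$AIC,
          npar = f$npar, converged = f$convergence$converged)),
        comparisons = lapply(ladder$comparisons, function(cm)
          list(lrt = cm$lrt, df = cm$df, p_value = cm$p_value,
               delta_aic = cm$delta_aic, preferred = cm$preferred)),
        derived_best = suppressWarnings(derived_estimates(best_fit))
      )
      jsonlite::write_json(report, file.path(cfg$out_dir, "fit_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      status$genetic <- "ok"
    }
    if ("phenotypic" %in% cfg$analyses) {
      long <- data.frame(
        y = c(pairs$m1_trait2, pairs$m2_trait2),
        x = c(pairs$m1_trait1, pairs$m2_trait1),
        sex = c(pairs$m1_sex, pairs$m2_sex),
        by_decade = c(pairs$m1_by - preset$covariates$ref_year,
                      pairs$m2_by - preset$covariates$ref_year) / 10,
        pair = c(pairs$pair_id, pairs$pair_id)
      )
      ols <- ols_cluster_robust(long$y, long$x,
                                long[, c("sex", "by_decade")], long$pair)
      res <- data.frame(outcome = preset$traits[2],
                        beta = ols$beta, se = ols$se,
                        lower = ols$ci[1], upper = ols$ci[2],
                        n = ols$n, n_clusters = ols$n_clusters)
      write_tsv_commented(res, file.path(cfg$out_dir, "phenotypic_report.tsv"),
                          meta)
      jsonlite::write_json(as.list(res),
                           file.path(cfg$out_dir, "phenotypic_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      status$phenotypic <- "ok"
    }
  } else {  # registry preset
    persons <- simulate_registry(cfg$n %||% preset$config$n %||% 100000,
                                 preset$config, seed = cfg$seed)
    write_tsv_commented(persons, file.path(cfg$out_dir, "registry.tsv"), meta)
    status$simulate <- "ok"
    if ("phenotypic" %in% cfg$analyses) {
      outcomes <- sub("^event_age_", "",
                      grep("^event_age_", names(persons), value = TRUE))
      tab <- do.call(rbind, lapply(outcomes, function(oc) {
        rows <- build_counting_process(persons, oc,
                                       ref_year = preset$config$ref_year)
        cf <- cox_fit(rows)
        data.frame(outcome = oc, hr = cf$hr[["exposed"]],
                   lower = cf$ci["exposed", "lower"],
                   upper = cf$ci["exposed", "upper"],
                   n_events = cf$n_events, stringsAsFactors = FALSE)
      }))
      rendered <- render_tables(epi = tab)
      writeLines(rendered$text, file.path(cfg$out_dir, "epi_report.txt"))
      write_tsv_commented(tab, file.path(cfg$out_dir, "epi_report.tsv"), meta)
      jsonlite::write_json(tab, file.path(cfg$out_dir, "epi_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      # cumulative incidence of the combined outcome by diagnosis group
      oc <- if ("any_substance" %in% outcomes) "any_substance" else outcomes[1]
      rows <- build_counting_process(persons, oc,
                                     ref_year = preset$config$ref_year)
      grp <- ifelse(is.na(persons$ocd_dx_age[match(rows$person_id,
                                                   persons$person_id)]),
                    "unaffected", "ocd")
      km <- km_cumulative_incidence(rows, grp,
                                    eval_ages = seq(15, 60, by = 0.5))
      write_tsv_commented(km, file.path(cfg$out_dir, "km_curves.tsv"), meta)
      status$phenotypic <- "ok"
    }
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    config = cfg,
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("kinace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = status
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
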