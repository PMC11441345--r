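#' Configuration of an end-to-end profile-network run
#'
#' @param input A [response_matrix()], a data frame / matrix of item scores,
#'   or a path to a delimited file readable by [load_responses()].
#' @param out_dir Optional output directory for artifacts (created if
#'   needed); when NULL nothing is written.
#' @param rule The diagnostic [profile_rule()] (PHQ-9 defaults).
#' @param control The estimation [ggm_control()].
#' @param boot Optional [boot_config()]; when supplied, a stability analysis
#'   runs for every selected profile.
#' @param selectors Profiles to analyse: integer frequency ranks (default
#'   1:3, the most prevalent profiles) or a character vector of presence
#'   pattern strings.
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it (Lehmer sequence), so stages can be rerun in isolation.
#' @param min_n Per-profile estimation floor (default 10).
#' @param items Item column names when \code{input} is a file path.
#' @param verbose Emit progress messages (default TRUE).
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input, out_dir = NULL, rule = profile_rule(),
                            control = ggm_control(), boot = NULL,
                            selectors = 1:3, seed = 42L, min_n = 10L,
                            items = paste0("phq", 1:9), verbose = TRUE) {
  stopifnot(inherits(rule, "profile_rule"), inherits(control, "ggm_control"))
  if (!is.null(boot)) stopifnot(inherits(boot, "boot_config"))
  if (length(selectors) < 1L) stop("selectors must not be empty")
  structure(list(input = input, out_dir = out_dir, rule = rule,
                 control = control, boot = boot, selectors = selectors,
                 seed = as.integer(seed), min_n = as.integer(min_n),
                 items = items, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full profile-network pipeline
#'
#' Executes catalog enumeration, cohort loading and matching, the profile
#' frequency table, and for each selected profile: network estimation
#' (regularized EBIC-glasso first, falling back to the significance-
#' thresholded non-regularized estimator when the regularized path fails,
#' with the fallback logged), strength centrality, layout, and — when a
#' bootstrap configuration is supplied — the stability analysis. All
#' artifacts are written under \code{out_dir} when given.
#'
#' @param config A [pipeline_config()].
#' @return An object of class \code{"run_report"}: list with stage counts,
#'   the frequency table, per-profile results, a log, and the configuration
#'   fingerprint.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (config$verbose) message(msg)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  catalog <- enumerate_profiles(config$rule)
  say("catalog: %d eligible profiles over %d items",
      length(catalog$pattern), config$rule$n_items)
  if (!is.null(out_dir)) write_catalog(catalog, file.path(out_dir,
                                                          "catalog.csv"))

  responses <- config$input
  if (is.character(responses)) {
    responses <- load_responses(responses, items = config$items)
  } else if (!inherits(responses, "response_matrix")) {
    responses <- response_matrix(responses,
                                 max_item_score = config$rule$max_item_score)
  }
  n_read <- nrow(responses$scores) + attr(responses, "n_excluded") %||% 0L
  say("input: %d rows read, %d excluded at validation",
      n_read, attr(responses, "n_excluded") %||% 0L)

  responses <- match_profiles(responses, catalog)
  n_included <- sum(responses$included, na.rm = TRUE)
  say("inclusion: %d of %d respondents meet the rule",
      n_included, nrow(responses$scores))
  if (!is.null(out_dir)) write_responses(responses,
                                         file.path(out_dir, "matched.csv"))

  freq <- suppressWarnings(profile_frequencies(responses, catalog))
  say("observed: %d distinct profiles", nrow(freq))
  if (!is.null(out_dir)) {
    write.csv(as.data.frame(freq), file.path(out_dir, "frequency.csv"),
              row.names = FALSE)
  }

  profiles <- list()
  if (n_included == 0L) {
    say("warning: no included respondents; skipping network stages")
  } else {
    sel <- config$selectors
    if (is.character(sel)) {
      ids <- profile_id_of(catalog, sel)
      ranks <- match(ids, freq$profile_id)
    } else {
      ranks <- as.integer(sel)
      ids <- freq$profile_id[ranks]
    }
    for (i in seq_along(ids)) {
      pid <- ids[i]
      rk <- ranks[i]
      if (is.na(pid) || is.na(rk) || rk > nrow(freq)) {
        say("selector %s: no matching observed profile, skipped",
            as.character(config$selectors[i]))
        next
      }
      res <- analyse_profile(responses, catalog, pid, rk, config, say)
      if (!is.null(res)) profiles[[length(profiles) + 1L]] <- res
    }
  }

  report <- structure(list(
    counts = list(rows_read = n_read,
                  rows_invalid = attr(responses, "n_excluded") %||% 0L,
                  n_respondents = nrow(responses$scores),
                  n_included = n_included,
                  n_observed_profiles = nrow(freq),
                  catalog_size = length(catalog$pattern)),
    rule = config$rule,
    frequencies = freq,
    profiles = profiles,
    seed = config$seed,
    log = log,
    package_version = as.character(utils::packageVersion("symptomnet"))),
    class = "run_report")

  if (!is.null(out_dir)) {
    writeLines(render_report(report), file.path(out_dir, "report.md"))
    jsonlite::write_json(
      list(counts = report$counts, log = log,
           package_version = report$package_version),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# estimate one profile's network (+ optional stability), with fallback
analyse_profile <- function(responses, catalog, pid, rank, config, say) {
  sub <- tryCatch(
    profile_subsample(responses, catalog, pid, min_n = config$min_n),
    error = function(e) {
      say("profile %d (rank %d): %s", pid, rank, conditionMessage(e))
      NULL
    })
  if (is.null(sub)) return(NULL)
  say("profile %d (rank %d): n = %d, %d present items",
      pid, rank, nrow(sub), ncol(sub))
  net <- tryCatch(
    suppressWarnings(symptom_network(sub, method = "ebic_glasso",
                                     control = config$control)),
    error = function(e) NULL)
  fallback <- is.null(net)
  if (fallback) {
    say("profile %d: regularized estimation failed; falling back to the %s",
        pid, "non-regularized threshold estimator")
    net <- suppressWarnings(symptom_network(sub, method = "nonreg",
                                            control = config$control))
  }
  net$dropped_items <- attr(sub, "dropped_items")
  cent <- strength_centrality(net)
  layout_seed <- derive_seed(config$seed, rank)
  lay <- network_layout(net, seed = layout_seed)
  stab <- NULL
  if (!is.null(config$boot)) {
    boot <- config$boot
    boot$seed <- derive_seed(config$seed, 100L + rank)
    stab <- tryCatch(
      network_stability(sub, config$control, boot, method = net$method),
      error = function(e) {
        say("profile %d: stability analysis failed (%s)", pid,
            conditionMessage(e))
        NULL
      })
    if (!is.null(stab)) {
      say("profile %d: CS coefficient %.2f (%s)", pid, stab$cs$cs,
          if (stab$cs$interpretable) "interpretable" else
            "not interpretable")
    }
  }
  if (!is.null(config$out_dir)) {
    pdir <- file.path(config$out_dir, sprintf("profile_rank%d", rank))
    if (!dir.exists(pdir)) dir.create(pdir)
    write_edge_list(net, file.path(pdir, "edges.csv"))
    write_centrality(net, file.path(pdir, "centrality.csv"))
    write_graphml(net, file.path(pdir, "network.graphml"),
                  seed = layout_seed)
    write_network_json(net, file.path(pdir, "network.json"),
                       seed = layout_seed)
    if (!is.null(stab)) write_stability_json(stab,
                                             file.path(pdir,
                                                       "stability.json"))
  }
  list(profile_id = pid, rank = rank, pattern = catalog$pattern[pid],
       n = nrow(sub), network = net, fallback = fallback,
       centrality = cent, layout = lay, stability = stab)
}

#' Render a run report as markdown
#'
#' Deterministic plain-text summary: catalog size, observed-profile count,
#' coverage of the top profiles, and per-profile sample size, method,
#' strongest symptoms and CS coefficient.
#'
#' @param report A [run_pipeline()] report.
#' @param top_m Number of top profiles in the coverage line (default 8).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report, top_m = 8L) {
  stopifnot(inherits(report, "run_report"))
  co <- report$counts
  lines <- c(
    "# Symptom profile network analysis",
    "",
    sprintf("- Theoretical catalog size: %d", co$catalog_size),
    sprintf("- Respondents read: %d (invalid rows excluded: %d)",
            co$rows_read, co$rows_invalid),
    sprintf("- Included respondents: %d", co$n_included),
    sprintf("- Distinct observed profiles: %d", co$n_observed_profiles))
  if (co$n_observed_profiles > 0L) {
    m <- min(top_m, co$n_observed_profiles)
    lines <- c(lines, sprintf(
      "- Coverage: top %d profiles account for %.1f%% of included cases",
      m, coverage(report$frequencies, m)))
  }
  for (pr in report$profiles) {
    cent <- pr$centrality[order(pr$centrality$rank), ]
    top3 <- paste(utils::head(cent$item, 3L), collapse = ", ")
    lines <- c(lines, "",
      sprintf("## Profile rank %d (catalog ID %d, pattern %s)",
              pr$rank, pr$profile_id, pr$pattern),
      sprintf("- n = %d; estimator: %s%s", pr$n, pr$network$method,
              if (pr$fallback) " (fallback after regularized failure)"
              else ""),
      sprintf("- Items in network: %d; strongest symptoms: %s",
              length(pr$network$items), top3))
    if (!is.null(pr$stability)) {
      lines <- c(lines, sprintf(
        "- CS coefficient: %.2f (%s)", pr$stability$cs$cs,
        if (pr$stability$cs$interpretable) "interpretable"
        else "not interpretable"))
    }
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
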