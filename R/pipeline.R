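#' Default configuration for the full analysis pipeline
#'
#' Collects every tunable surfaced by the individual stages: EBIC gamma and
#' symmetrization rule for the Ising fits, CLPN penalty selection, walktrap
#' walk length, goldbricker thresholds, display edge threshold (0.24, the
#' published figure convention), density denominator flag, and the
#' case-dropping bootstrap settings.
#'
#' @param seed Base integer seed; all stage seeds are derived from it.
#' @return Named list of settings.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    gamma = 0.25,
    rule = "AND",
    selection = "cv",
    walk_length = 4,
    goldbricker = list(p_threshold = 0.05, proportion_threshold = 0.25,
                       cor_min = 0.5),
    display_threshold = 0.24,
    density_include_diagonal = TRUE,
    stability = list(
      enabled = TRUE,
      n_boot = 1000,
      drop_grid = seq(0.05, 0.75, by = 0.05),
      indices = c("out_strength", "in_strength"),
      edge_ci = FALSE,
      edge_ci_n_boot = 1000))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full network-analysis workflow on a two-wave panel
#'
#' Executes, per group (diabetes / no diabetes): inclusion filtering,
#' group descriptives, item-redundancy screening per wave, wave-1 Ising
#' networks for three node sets (symptoms only, behaviours only, combined),
#' cross-lagged panel networks for two node sets (symptoms only, combined),
#' centrality and bridge tables (including the autoregressive-free and
#' display-thresholded views), walktrap communities on the combined Ising
#' networks, and (optionally) case-dropping bootstrap stability with
#' CS-coefficients. Every stage is a pure function of (panel, config, seed).
#'
#' @param panel A \code{"binary_panel"} (missing data allowed; the inclusion
#'   filter runs first).
#' @param config Settings list from [default_config()].
#' @return Object of class \code{"analysis_bundle"}; see the elements
#'   \code{descriptives}, \code{redundancy}, \code{ising}, \code{clpn},
#'   \code{metrics}, \code{communities}, \code{stability},
#'   \code{exclusion_log} and \code{manifest}.
#' @export
run_full_analysis <- function(panel, config = default_config()) {
  stopifnot(inherits(panel, "binary_panel"))
  cb <- panel$codebook
  dep_items <- names(cb$item_group)[cb$item_group == "depression"]
  beh_items <- names(cb$item_group)[cb$item_group == "behaviour"]
  partition <- codebook_partition(cb)
  groups <- c("diabetes", "no_diabetes")
  node_sets_cs <- list(symptoms = dep_items, behaviours = beh_items,
                       combined = cb$item_ids)
  node_sets_lg <- list(symptoms = dep_items, combined = cb$item_ids)

  filtered <- run_stage("inclusion_filter", apply_inclusion_filter(panel))
  pnl <- filtered$panel

  descr <- run_stage("descriptives", describe_panel(pnl))

  redundancy <- run_stage("goldbricker", {
    out <- list()
    for (g in groups) for (w in 1:2) {
      X <- panel_wave(panel_subset(pnl, pnl$group == g), w)
      out[[paste(g, "wave", w, sep = "_")]] <- goldbricker(
        X, p_threshold = config$goldbricker$p_threshold,
        proportion_threshold = config$goldbricker$proportion_threshold,
        cor_min = config$goldbricker$cor_min)
    }
    out
  })

  ising <- run_stage("ising", {
    out <- list()
    for (g in groups) for (ns in names(node_sets_cs)) {
      out[[paste(g, ns, sep = "_")]] <- ising_fit(
        pnl, gamma = config$gamma, rule = config$rule, wave = 1,
        group = g, items = node_sets_cs[[ns]])
    }
    out
  })

  clpn <- run_stage("clpn", {
    out <- list()
    k <- 0
    for (g in groups) for (ns in names(node_sets_lg)) {
      k <- k + 1
      out[[paste(g, ns, sep = "_")]] <- clpn_fit(
        pnl, group = g, items = node_sets_lg[[ns]],
        selection = config$selection, gamma = config$gamma,
        seed = derive_seed(config$seed, 100 + k))
    }
    out
  })

  metrics <- run_stage("metrics", {
    out <- list()
    for (nm in names(ising)) {
      fit <- ising[[nm]]
      m <- list(centrality = centrality_table(fit$weights),
                density = ising_density(fit))
      if (endsWith(nm, "combined"))
        m$bridge <- bridge_metrics(fit$weights, partition)
      out[[paste0("ising_", nm)]] <- m
    }
    for (nm in names(clpn)) {
      fit <- clpn[[nm]]
      no_ar <- drop_autoregressive(fit)
      out[[paste0("clpn_", nm)]] <- list(
        centrality = in_out_indices(fit),
        centrality_no_autoregressive = in_out_indices(no_ar),
        density = edge_density(
          fit, include_diagonal = config$density_include_diagonal),
        autoregressive = diag(fit$weights),
        thresholded_weights = threshold_edges(
          no_ar, config$display_threshold)$weights)
    }
    out
  })

  communities <- run_stage("communities", {
    out <- list()
    for (g in groups)
      out[[g]] <- walktrap_communities(
        ising[[paste(g, "combined", sep = "_")]]$weights,
        t = config$walk_length)
    out
  })

  stability <- NULL
  if (isTRUE(config$stability$enabled)) {
    stability <- run_stage("stability", {
      out <- list()
      k <- 0
      for (g in groups) for (index in config$stability$indices) {
        k <- k + 1
        cd <- case_drop_bootstrap(
          pnl, estimator = "clpn", index = index,
          drop_grid = config$stability$drop_grid,
          n_boot = config$stability$n_boot,
          seed = derive_seed(config$seed, 200 + k), group = g,
          fit_args = list(selection = config$selection,
                          gamma = config$gamma,
                          seed = derive_seed(config$seed, 300 + k)))
        out[[paste(g, index, sep = "_")]] <-
          list(case_drop = cd, cs = cs_coefficient(cd))
      }
      if (isTRUE(config$stability$edge_ci)) {
        for (g in groups)
          out[[paste0(g, "_edge_ci")]] <- edge_ci_bootstrap(
            pnl, estimator = "clpn",
            n_boot = config$stability$edge_ci_n_boot,
            seed = derive_seed(config$seed, 400), group = g,
            fit_args = list(selection = config$selection,
                            gamma = config$gamma,
                            seed = derive_seed(config$seed, 401)))
      }
      out
    })
  }

  bundle <- structure(
    list(descriptives = descr, redundancy = redundancy, ising = ising,
         clpn = clpn, metrics = metrics, communities = communities,
         stability = stability, exclusion_log = filtered$exclusion_log,
         manifest = list(
           seed = config$seed, config = config,
           n_subjects = n_subjects(pnl),
           package_version = as.character(utils::packageVersion("panelnet")))),
    class = "analysis_bundle")
  bundle$manifest$hash <- bundle_hash(bundle)
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Analysis bundle\n")
  cat(sprintf("  subjects retained: %d (of %d)\n",
              x$exclusion_log$retained, x$exclusion_log$input))
  cat(sprintf("  cross-sectional networks: %d; longitudinal networks: %d\n",
              length(x$ising), length(x$clpn)))
  if (!is.null(x$stability)) {
    cs <- vapply(x$stability[grepl("_(in|out)_", names(x$stability))],
                 function(s) s$cs, numeric(1))
    if (length(cs))
      cat("  CS-coefficients:",
          paste(sprintf("%s=%.2f", names(cs), cs), collapse = ", "), "\n")
  }
  cat(sprintf("  manifest hash: %s\n", x$manifest$hash))
  invisible(x)
}

# Serialize a bundle's numeric content to a canonical JSON string.
bundle_serialize <- function(bundle) {
  strip <- function(x) {
    if (inherits(x, c("ising_net", "clpn_net", "case_drop", "edge_ci",
                      "redundancy_report", "community_partition")))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::toJSON(strip(unclass(bundle)), digits = NA, force = TRUE,
                   auto_unbox = TRUE, na = "null")
}

#' Deterministic content hash of an analysis bundle
#'
#' Polynomial rolling hash (two co-prime moduli, exact double arithmetic) of
#' the bundle's canonical JSON serialization; two runs with the same panel,
#' config and seed produce the same hash.
#'
#' @param bundle An \code{"analysis_bundle"}.
#' @return Hex string.
#' @export
bundle_hash <- function(bundle) {
  b <- bundle
  b$manifest$hash <- NULL
  s <- bundle_serialize(b)
  bytes <- as.numeric(utf8ToInt(s))
  roll <- function(M) {
    base <- 131
    chunk <- 1024L
    pows <- numeric(chunk)          # pows[i] = base^(chunk - i) mod M
    pows[chunk] <- 1
    for (i in (chunk - 1):1) pows[i] <- (pows[i + 1] * base) %% M
    h <- 0
    n <- length(bytes)
    ix <- 1L
    while (ix <= n) {
      jx <- min(ix + chunk - 1L, n)
      L <- jx - ix + 1L
      pw <- pows[(chunk - L + 1L):chunk]
      base_pow_L <- (pows[chunk - L + 1L] * base) %% M
      h <- (h * base_pow_L + sum(bytes[ix:jx] * pw) %% M) %% M
      ix <- jx + 1L
    }
    h
  }
  # both moduli are primes below 2^26, keeping all products exact in doubles
  sprintf("%07x%07x", roll(67108859), roll(67108837))
}

#' Write an analysis bundle to a results directory
#'
#' Networks and centrality tables as CSV; descriptives, redundancy,
#' communities, stability, exclusion log and manifest as JSON.
#'
#' @param bundle An \code{"analysis_bundle"}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wj <- function(x, name)
    jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                         digits = NA, force = TRUE, na = "null", pretty = TRUE)
  for (nm in names(bundle$ising))
    utils::write.csv(bundle$ising[[nm]]$weights,
                     file.path(dir, paste0("ising_", nm, ".csv")))
  for (nm in names(bundle$clpn))
    utils::write.csv(bundle$clpn[[nm]]$weights,
                     file.path(dir, paste0("clpn_", nm, ".csv")))
  for (nm in names(bundle$metrics)) {
    m <- bundle$metrics[[nm]]
    utils::write.csv(m$centrality,
                     file.path(dir, paste0("centrality_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$descriptives$table,
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  wj(lapply(bundle$redundancy, function(r)
    list(pairs = r$pairs, suggested_reductions = r$suggested_reductions)),
    "redundancy.json")
  wj(lapply(bundle$communities, function(cm)
    list(assignment = as.list(cm$assignment), modularity = cm$modularity,
         t = cm$t)), "communities.json")
  if (!is.null(bundle$stability))
    wj(lapply(bundle$stability, function(s) {
      if (inherits(s, "edge_ci")) list(edges = s$edges, n_boot = s$n_boot)
      else list(cs = s$cs, drop_grid = s$case_drop$drop_grid,
                median_correlation = vapply(
                  s$case_drop$correlations,
                  function(v) stats::median(v, na.rm = TRUE), numeric(1)))
    }), "stability.json")
  wj(bundle$exclusion_log, "exclusion_log.json")
  wj(bundle$manifest, "manifest.json")
  invisible(dir)
}
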