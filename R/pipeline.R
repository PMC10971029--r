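#' Analysis configuration
#'
#' Bundles every knob of the variant-comparison pipeline. `variants` is a
#' named list: variant name -> list of replicate entries, each either a
#' [traj_ensemble()] or a file path (read with [read_ensemble()]; a path
#' entry may also be a list `list(path =, replicate =, temperature =)`).
#' Exactly one variant name is the wild-type reference (`wt`).
#'
#' @param variants named list of replicate lists (see Details).
#' @param wt name of the wild-type variant (default `"WT"`).
#' @param reference a [structure3d()] to superpose onto; default: the
#'   first frame of the first wild-type replicate (the initial wild-type
#'   conformation).
#' @param fit_selection selection used for superposition (default: the
#'   fixed chain's C-alpha atoms, `"chain A and name CA"`).
#' @param pca_selection selection analysed by PCA and RMSD (default: the
#'   mobile chain's C-alpha atoms, `"chain B and name CA"`).
#' @param domains named list of selection expressions defining domains for
#'   the energy decomposition.
#' @param domain_pairs named list of character pairs
#'   `c(domain_a, domain_b)`; each pair gets an interaction-energy series
#'   and a significance call. Names like `"iSH2:catalytic"` become report
#'   columns.
#' @param monitor_pairs list of [monitor_pair()]s (or `NULL` to skip).
#' @param parameters a `parameter_table`, a path to one, or a named list
#'   of either keyed by variant name (when variants carry their own
#'   parameterisation, as the synthetic charge-perturbed scenarios do).
#'   `NULL` skips the energy stage.
#' @param equilibration_fraction initial fraction of each replicate
#'   discarded (default 1/3: the final two-thirds are analysed).
#' @param pca_pooling `"pooled"` (one basis over wild type plus all
#'   variants, keeping medians comparable) or `"wt_only"`.
#' @param n_modes PCs reported (default 3).
#' @param temperature analyse only ensembles at this temperature
#'   (default 300; use `NULL` to keep everything).
#' @param stats_params list: `m_per_draw` (100), `repetitions` (1000),
#'   `alpha` (1e-6), `seed` (1).
#' @param switching a [switching_spec()].
#' @param fel_pair PC pair for the free-energy landscapes (default 1, 2).
#' @param fel_bins bins per FEL axis (default 50).
#' @param frame_interval frame interval in ps used when reading files.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(variants, wt = "WT", reference = NULL,
                            fit_selection = "chain A and name CA",
                            pca_selection = "chain B and name CA",
                            domains = list(
                              nSH2 = "chain B and resid 317-430 and name CA",
                              iSH2 = "chain B and resid 440-600 and name CA",
                              catalytic = "chain A and name CA"),
                            domain_pairs = list(
                              "iSH2:catalytic" = c("iSH2", "catalytic"),
                              "nSH2:catalytic" = c("nSH2", "catalytic")),
                            monitor_pairs = NULL, parameters = NULL,
                            equilibration_fraction = 1 / 3,
                            pca_pooling = c("pooled", "wt_only"),
                            n_modes = 3L, temperature = 300,
                            stats_params = list(), switching = switching_spec(),
                            fel_pair = c(1L, 2L), fel_bins = 50L,
                            frame_interval = 2) {
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("`variants` must be a named list")
  if (!wt %in% names(variants))
    stop("wild-type variant '", wt, "' not present in `variants`")
  sp <- utils::modifyList(list(m_per_draw = 100L, repetitions = 1000L,
                               alpha = 1e-6, seed = 1L), stats_params)
  structure(list(variants = variants, wt = wt, reference = reference,
                 fit_selection = fit_selection, pca_selection = pca_selection,
                 domains = domains, domain_pairs = domain_pairs,
                 monitor_pairs = monitor_pairs, parameters = parameters,
                 equilibration_fraction = equilibration_fraction,
                 pca_pooling = match.arg(pca_pooling),
                 n_modes = as.integer(n_modes), temperature = temperature,
                 stats_params = sp, switching = switching,
                 fel_pair = as.integer(fel_pair), fel_bins = as.integer(fel_bins),
                 frame_interval = frame_interval),
            class = "analysis_config")
}

load_variant_ensembles <- function(entries, name, config) {
  out <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (inherits(e, "traj_ensemble")) {
      ens <- e
    } else if (is.character(e)) {
      ens <- read_ensemble(e, frame_interval = config$frame_interval,
                           label = name, replicate = i)
    } else if (is.list(e) && !is.null(e$path)) {
      ens <- read_ensemble(e$path, frame_interval = config$frame_interval,
                           label = name,
                           replicate = if (is.null(e$replicate)) i else e$replicate,
                           temperature = if (is.null(e$temperature)) 300 else e$temperature)
    } else stop("variant '", name, "' replicate ", i,
                ": expected a traj_ensemble, a path, or list(path=...)")
    out[[length(out) + 1L]] <- ens
  }
  if (!is.null(config$temperature)) {
    keep <- vapply(out, function(x) isTRUE(all.equal(x$temperature, config$temperature)),
                   logical(1))
    out <- out[keep]
  }
  if (!length(out))
    stop("variant '", name, "' has no ensembles at the analysis temperature")
  out
}

variant_parameters <- function(config, name) {
  p <- config$parameters
  if (is.null(p)) return(NULL)
  if (is.list(p) && !is.data.frame(p)) {
    p <- if (!is.null(p[[name]])) p[[name]] else p[["default"]]
    if (is.null(p)) stop("no parameter table for variant '", name, "'")
  }
  if (is.character(p)) p <- read_parameter_table(p)
  as_parameter_table(p)
}

#' Run the full variant-comparison analysis
#'
#' Orchestrates the pipeline: load ensembles, discard equilibration,
#' superpose every frame onto the reference (fit selection), fit a shared
#' PCA basis, project each variant, classify PC shifts against the wild
#' type at the one-sigma rule, compute RMSD summaries, distance monitors,
#' per-domain-pair switched nonbonded interaction energies, the
#' down-sampled resampling test for each variant-vs-WT energy comparison,
#' and PC-pair free-energy landscapes. Deterministic given the config
#' (per-variant test seeds are derived from `stats_params$seed` and the
#' variant name, so results for one variant do not depend on which other
#' variants are in the manifest).
#'
#' @param config an [analysis_config()].
#' @return object of class `variant_report_set`: per non-WT variant a
#'   report with `pc_shifts` (list of `pc_shift_call`), `interactions`
#'   (per domain pair: call, median ΔE, median t, p), `rmsd_median`,
#'   `monitors`; plus shared `basis`, `projections`, `fels`,
#'   `rmsd_series`, `energies`, `wt` name and the `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  vnames <- names(config$variants)
  ensembles <- lapply(vnames, function(nm)
    load_variant_ensembles(config$variants[[nm]], nm, config))
  names(ensembles) <- vnames
  ensembles <- lapply(ensembles, function(reps)
    lapply(reps, drop_equilibration, fraction = config$equilibration_fraction))

  reference <- config$reference
  if (is.null(reference)) reference <- get_frame(ensembles[[config$wt]][[1]], 1L)
  ensembles <- lapply(ensembles, function(reps)
    lapply(reps, superpose_ensemble, reference = reference,
           fit_selection = config$fit_selection))

  pool <- if (config$pca_pooling == "pooled") unlist(ensembles, recursive = FALSE)
          else ensembles[[config$wt]]
  basis <- fit_modes(pool, config$pca_selection, config$n_modes)

  projections <- lapply(ensembles, function(reps)
    lapply(reps, project_ensemble, basis = basis))

  rmsds <- lapply(ensembles, function(reps)
    lapply(reps, rmsd_series, reference = reference,
           report_selection = config$pca_selection))

  monitors <- NULL
  if (!is.null(config$monitor_pairs)) {
    monitors <- lapply(ensembles, function(reps) {
      per_rep <- lapply(reps, distance_series, pairs = config$monitor_pairs)
      lapply(seq_along(config$monitor_pairs), function(j) {
        m <- per_rep[[1]][[j]]
        m$series <- unlist(lapply(per_rep, function(x) x[[j]]$series))
        m
      })
    })
  }

  energies <- NULL
  tests <- NULL
  if (!is.null(config$parameters)) {
    energies <- lapply(vnames, function(nm) {
      params <- variant_parameters(config, nm)
      per_pair <- lapply(names(config$domain_pairs), function(pn) {
        pr <- config$domain_pairs[[pn]]
        series <- lapply(ensembles[[nm]], function(e)
          interaction_energy_series(e, config$domains[[pr[1]]],
                                    config$domains[[pr[2]]], params,
                                    config$switching, labels = pr))
        pool_energy_series(series)
      })
      names(per_pair) <- names(config$domain_pairs)
      per_pair
    })
    names(energies) <- vnames
    sp <- config$stats_params
    tests <- lapply(setdiff(vnames, config$wt), function(nm) {
      per_pair <- lapply(names(config$domain_pairs), function(pn) {
        downsample_test(energies[[nm]][[pn]]$values,
                        energies[[config$wt]][[pn]]$values,
                        m_per_draw = sp$m_per_draw, repetitions = sp$repetitions,
                        seed = derive_seed(sp$seed, nm, pn), alpha = sp$alpha)
      })
      names(per_pair) <- names(config$domain_pairs)
      per_pair
    })
    names(tests) <- setdiff(vnames, config$wt)
  }

  fels <- lapply(projections, compute_fel, pc_pair = config$fel_pair,
                 bins = config$fel_bins)

  wt_proj <- projections[[config$wt]]
  reports <- lapply(setdiff(vnames, config$wt), function(nm) {
    pcs <- lapply(seq_len(ncol(basis$vectors)), function(k)
      call_pc_shift(projections[[nm]], wt_proj, k))
    inter <- NULL
    if (!is.null(energies)) {
      inter <- lapply(names(config$domain_pairs), function(pn) {
        tst <- tests[[nm]][[pn]]
        list(pair = pn,
             call = interaction_call(energies[[nm]][[pn]],
                                     energies[[config$wt]][[pn]], tst),
             median_delta_e = stats::median(energies[[nm]][[pn]]$values) -
               stats::median(energies[[config$wt]][[pn]]$values),
             median_t = tst$median_t, p_value = tst$p_value)
      })
      names(inter) <- names(config$domain_pairs)
    }
    list(variant = nm,
         pc_shifts = pcs,
         delta_pcs = {
           calls <- vapply(pcs, `[[`, "", "call")
           calls <- calls[calls != "none"]
           if (length(calls)) paste(calls, collapse = ", ") else "none"
         },
         interactions = inter,
         rmsd_median = stats::median(unlist(lapply(rmsds[[nm]], `[[`, "values"))),
         monitors = if (!is.null(monitors))
           lapply(monitors[[nm]], summarize_monitor))
  })
  names(reports) <- setdiff(vnames, config$wt)

  structure(list(reports = reports, basis = basis, projections = projections,
                 fels = fels, rmsd_series = rmsds, energies = energies,
                 tests = tests, wt = config$wt,
                 wt_rmsd_median = stats::median(unlist(lapply(rmsds[[config$wt]],
                                                              `[[`, "values"))),
                 config = config),
            class = "variant_report_set")
}

#' @export
print.variant_report_set <- function(x, ...) {
  cat(sprintf("variant_report_set: %d variant(s) vs %s\n",
              length(x$reports), x$wt))
  cat(render_report(x, format = "markdown"), sep = "\n")
  invisible(x)
}

#' @export
summary.variant_report_set <- function(object, ...) {
  print(object$basis)
  print(object)
  invisible(object)
}

report_table <- function(reports) {
  rows <- lapply(reports$reports, function(r) {
    row <- list(variant = r$variant, delta_pcs = r$delta_pcs)
    for (k in seq_along(r$pc_shifts)) {
      s <- r$pc_shifts[[k]]
      row[[sprintf("pc%d_median", k)]] <- signif(s$variant_median, 6)
      row[[sprintf("pc%d_wt_sigma", k)]] <- signif(s$wt_sd, 6)
    }
    if (!is.null(r$interactions)) {
      for (pn in names(r$interactions)) {
        it <- r$interactions[[pn]]
        key <- gsub("[^A-Za-z0-9]+", "_", pn)
        row[[paste0(key, "_call")]] <- it$call
        row[[paste0(key, "_median_dE")]] <- signif(it$median_delta_e, 6)
        row[[paste0(key, "_median_t")]] <- signif(it$median_t, 6)
        row[[paste0(key, "_p")]] <- signif(it$p_value, 6)
      }
    }
    row$rmsd_median_A <- signif(r$rmsd_median, 6)
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(cols, function(cn)
    vapply(rows, function(r) as.character(if (is.null(r[[cn]])) NA else r[[cn]]), "")),
    stringsAsFactors = FALSE)
  names(df) <- cols
  rownames(df) <- NULL
  df
}

#' Render a variant report
#'
#' One row per variant; columns follow the variant-table convention: PC
#' shift calls (joined like `"+PC1, -PC3"`), per-domain-pair interaction
#' calls (`"+"` stronger, `"-"` weaker, `"n.s."` not significant) with
#' median energy difference, median t and p, and the median RMSD on the
#' reporting selection. Qualitative level columns (e.g. binning RMSD into
#' Low/High) are not built in; bin the numeric columns yourself if needed.
#'
#' @param reports a `variant_report_set` from [run_analysis()].
#' @param format `"tsv"`, `"json"`, or `"markdown"`.
#' @param file optional output path; if `NULL` the rendering is returned
#'   as a character vector (or JSON string).
#' @return the rendering (invisibly if written to `file`).
#' @export
render_report <- function(reports, format = c("tsv", "json", "markdown"),
                          file = NULL) {
  format <- match.arg(format)
  if (!length(reports$reports)) stop("empty report set")
  df <- report_table(reports)
  out <- switch(format,
    tsv = c(paste(names(df), collapse = "\t"),
            apply(df, 1L, paste, collapse = "\t")),
    json = as.character(jsonlite::toJSON(df, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA)),
    markdown = {
      hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
      body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      c(hdr, sep, body)
    })
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
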