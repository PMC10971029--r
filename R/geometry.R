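#' Specify a residue-pair distance monitor
#'
#' A monitor pair names two chain-qualified C-alpha atoms whose Euclidean
#' distance is tracked per frame, e.g. to assess local unfolding at the end
#' of a helical domain.
#'
#' @param chain_a,resno_a chain id and author residue number of the first atom.
#' @param chain_b,resno_b chain id and author residue number of the second atom.
#' @param atom_name atom name (default `"CA"`).
#' @param label optional label; defaults to `"A/123-B/456"` style.
#' @return a `monitor_pair` list.
#' @export
monitor_pair <- function(chain_a, resno_a, chain_b, resno_b,
                         atom_name = "CA", label = NULL) {
  if (is.null(label))
    label <- sprintf("%s/%d-%s/%d", chain_a, resno_a, chain_b, resno_b)
  structure(list(chain_a = chain_a, resno_a = as.integer(resno_a),
                 chain_b = chain_b, resno_b = as.integer(resno_b),
                 atom_name = atom_name, label = label),
            class = "monitor_pair")
}

#' Default inter-helix distance monitor pairs
#'
#' The three monitors used for the PIK3R1:PIK3CA complex: K567 to E453,
#' R577 to Y452, and V445 to L584 (PIK3R1 residue first). The source text
#' qualifies only the first pair's second residue as PIK3CA; under
#' `reading = "verbatim"` the unqualified second residues inherit that
#' chain, under `reading = "intra_mobile"` they are taken as PIK3R1
#' (inter-helix within the mobile chain, matching the monitors' stated
#' purpose). Both readings are provided; neither is silently preferred.
#'
#' @param mobile_chain chain id of PIK3R1 in your files (default `"B"`).
#' @param fixed_chain chain id of PIK3CA (default `"A"`).
#' @param reading `"verbatim"` or `"intra_mobile"` (see Details).
#' @return list of [monitor_pair()] objects.
#' @export
default_monitor_pairs <- function(mobile_chain = "B", fixed_chain = "A",
                                  reading = c("verbatim", "intra_mobile")) {
  reading <- match.arg(reading)
  second <- if (reading == "verbatim") fixed_chain else mobile_chain
  list(monitor_pair(mobile_chain, 567L, fixed_chain, 453L),
       monitor_pair(mobile_chain, 577L, second, 452L),
       monitor_pair(mobile_chain, 445L, second, 584L))
}

resolve_monitor_atom <- function(atoms, chain, resno, atom_name, spec_label) {
  hit <- which(atoms$chain_id == chain & atoms$residue_number == resno &
               atoms$atom_name == atom_name)
  if (length(hit) != 1L)
    stop(sprintf("monitor spec %s (%s/%d %s) resolves to %d atoms; need exactly 1",
                 spec_label, chain, resno, atom_name, length(hit)))
  hit
}

#' Distance monitor series over an ensemble
#'
#' Euclidean C-alpha to C-alpha distance per frame for each pair spec.
#'
#' @param ensemble a [traj_ensemble()].
#' @param pairs a [monitor_pair()] or list of them.
#' @return list of `distance_monitor` objects, each with `pair`
#'   (the spec), `label` and `series` (length T, Angstrom, all > 0).
#' @export
distance_series <- function(ensemble, pairs) {
  if (inherits(pairs, "monitor_pair")) pairs <- list(pairs)
  atoms <- ensemble$atoms
  lapply(pairs, function(p) {
    ia <- resolve_monitor_atom(atoms, p$chain_a, p$resno_a, p$atom_name, p$label)
    ib <- resolve_monitor_atom(atoms, p$chain_b, p$resno_b, p$atom_name, p$label)
    if (ia == ib) stop("monitor pair ", p$label, " names the same atom twice")
    d <- sqrt(rowSums((matrix(ensemble$frames[, ia, ], ncol = 3L) -
                       matrix(ensemble$frames[, ib, ], ncol = 3L))^2))
    structure(list(pair = p, label = p$label, series = d,
                   ensemble_label = ensemble$label,
                   replicate = ensemble$replicate),
              class = "distance_monitor")
  })
}

#' @export
print.distance_monitor <- function(x, ...) {
  cat(sprintf("distance_monitor %s: %d frames, median %.2f A\n",
              x$label, length(x$series), stats::median(x$series)))
  invisible(x)
}

#' Summary statistics of a distance monitor
#' @param monitor a `distance_monitor` (or bare numeric series).
#' @return named list: `median`, `mean`, `sd`, `min`, `max` (Angstrom).
#' @export
summarize_monitor <- function(monitor) {
  s <- if (inherits(monitor, "distance_monitor")) monitor$series else as.numeric(monitor)
  if (!length(s)) stop("empty monitor series")
  list(median = stats::median(s), mean = mean(s),
       sd = if (length(s) > 1L) stats::sd(s) else 0,
       min = min(s), max = max(s))
}

#' Export monitors as tidy TSV
#' @param monitors list of `distance_monitor` objects.
#' @param path output TSV path (columns: frame, pair_label, distance_A).
#' @return `path`, invisibly.
#' @export
write_monitors <- function(monitors, path) {
  if (inherits(monitors, "distance_monitor")) monitors <- list(monitors)
  df <- do.call(rbind, lapply(monitors, function(m)
    data.frame(frame = seq_along(m$series), pair_label = m$label,
               distance_A = m$series, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
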