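# End-to-end orchestration: simulate (or ingest) -> ancestral state
# estimation -> change calling -> tallies -> rate comparison -> duplication
# association -> term enrichment, with a machine-readable manifest and
# summary. Stages are the exported functions; the pipeline only sequences
# them, so each stage is independently invocable with identical results.

#' Run the full organellar-targeting-evolution pipeline
#'
#' Runs every stage on a simulated data set (or a pre-built `sim_dataset`):
#' per-orthogroup reconciliation and ancestral character estimation (ARD by
#' default), change calling with the retention filter, species-branch
#' tallies, normalized-rate comparison, high-confidence duplication
#' association test, per-million-year change rates, and term enrichment of
#' changed orthogroups. All randomness derives from `seed`, so reruns are
#' byte-identical.
#'
#' @param config A [sim_config()] describing the data set to simulate, or an
#'   existing `sim_dataset` from [simulate_dataset()].
#' @param seed Integer seed controlling simulation and resampling.
#' @param model Ancestral-state model, `"ARD"` (default) or `"ER"`.
#' @param mode Species-branch mapping mode, `"mrca"` (default) or `"split"`.
#' @param n_resamples Matched Monte Carlo resamples (default 1000).
#' @param n_dated_nodes Number of internal nodes used for per-My rates
#'   (default 10, fewer when the tree is small).
#' @param outdir Optional directory; when given, stage outputs are written as
#'   TSV plus a JSON run manifest.
#' @return An object of class `orgflux_run`: list with `data`, `fits`,
#'   `events`, `tallies`, `rates`, `rate_test`, `dup_records`, `dup_test`,
#'   `per_myr`, `enrichment`, `summary` and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1,
                         model = c("ARD", "ER"), mode = c("mrca", "split"),
                         n_resamples = 1000, n_dated_nodes = 10,
                         outdir = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  t0 <- Sys.time()
  timings <- list()

  if (inherits(config, "sim_dataset")) {
    ds <- config
  } else if (inherits(config, "sim_config")) {
    ds <- simulate_dataset(config, seed = seed)
  } else {
    abort("`config` must be a sim_config or sim_dataset")
  }
  timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")

  organelle <- ds$config$organelle
  states_all <- trait_states(ds$localization, organelle)

  t1 <- Sys.time()
  events_list <- list()
  rates_list <- list()
  records_list <- list()
  fossil_list <- list()
  fits <- list()
  for (og in ds$orthogroups) {
    recon <- lca_reconcile(og$gene_tree, ds$species_tree, og$gene_species_map)
    st <- states_all[og$gene_tree$tip.label]
    fit <- fit_mk(og$gene_tree, st, model = model)
    ev <- call_changes(fit, recon, organelle = organelle,
                       orthogroup = og$orthogroup, mode = mode)
    events_list[[og$orthogroup]] <- ev
    rates_list[[og$orthogroup]] <-
      collect_normalized_rates(recon, ev, orthogroup = og$orthogroup)
    records_list[[og$orthogroup]] <-
      select_high_confidence_nodes(recon, ev, orthogroup = og$orthogroup)
    fossil_list[[og$orthogroup]] <-
      find_fossil_duplicate_branches(recon, ds$wgd_branches, ev,
                                     orthogroup = og$orthogroup)
    fits[[og$orthogroup]] <- fit
  }
  events <- dplyr::bind_rows(events_list)
  rates <- dplyr::bind_rows(rates_list)
  records <- dplyr::bind_rows(records_list)
  if (nrow(records)) {
    records <- classify_duplication_origin(records, ds$wgd_branches,
                                           ds$species_tree)
  }
  fossil <- dplyr::bind_rows(fossil_list)
  timings$per_orthogroup <- as.numeric(Sys.time() - t1, units = "secs")

  t2 <- Sys.time()
  tallies <- tally_changes(events, ds$species_tree)

  rate_test <- NULL
  if (nrow(rates) && any(rates$has_change) && any(!rates$has_change)) {
    rate_test <- compare_rates(rates, n_resamples = n_resamples,
                               species_tree = ds$species_tree)
  }

  dup_test <- NULL
  if (nrow(records) && length(unique(records$class)) == 2L) {
    dup_test <- duplication_change_test(records, n_resamples = n_resamples)
  }

  dated <- dated_node_table(ds, n_dated_nodes)
  per_myr <- per_myr_rates(tallies[!tallies$terminal, , drop = FALSE],
                           dated, ds$species_tree,
                           root_age = ds$config$root_age)

  og_ids <- vapply(ds$orthogroups, `[[`, character(1), "orthogroup")
  targeted <- vapply(ds$orthogroups, function(og) any(og$tip_states == 1L),
                     logical(1))
  changed_called <- unique(events$orthogroup)
  background <- union(og_ids[targeted], changed_called)
  enrichment <- NULL
  if (length(changed_called) && nrow(ds$term_table)) {
    enrichment <- enrich(changed_called, background, ds$term_table)
  }
  timings$analyses <- as.numeric(Sys.time() - t2, units = "secs")

  summary <- list(
    n_orthogroups = length(ds$orthogroups),
    n_species = n_tips(ds$species_tree),
    n_events = nrow(events),
    n_gains = sum(events$direction == "gain"),
    n_losses = sum(events$direction == "loss"),
    freq_dup = if (!is.null(dup_test)) dup_test$freq_dup else NA_real_,
    freq_spec = if (!is.null(dup_test)) dup_test$freq_spec else NA_real_,
    dup_hypergeom_p = if (!is.null(dup_test)) dup_test$hypergeom_p else NA_real_,
    dup_mc_p = if (!is.null(dup_test)) dup_test$mc_p else NA_real_,
    rate_t_p = if (!is.null(rate_test)) rate_test$t_p else NA_real_,
    rate_mc_p = if (!is.null(rate_test)) rate_test$mc_p else NA_real_,
    total_per_my_median = if (nrow(per_myr)) stats::median(per_myr$total_per_my) else NA_real_,
    net_per_my_median = if (nrow(per_myr)) stats::median(per_myr$net_per_my) else NA_real_,
    n_enriched_terms = if (!is.null(enrichment)) sum(enrichment$significant) else 0L
  )

  manifest <- list(
    package = "orgflux",
    version = as.character(utils::packageVersion("orgflux")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, model = model, mode = mode, n_resamples = n_resamples,
    config = unclass(ds$config)[!vapply(unclass(ds$config), is.function,
                                        logical(1))],
    timings = timings
  )

  run <- structure(
    list(data = ds, fits = fits, events = events, tallies = tallies,
         rates = rates, rate_test = rate_test, dup_records = records,
         dup_test = dup_test, fossil_branches = fossil, per_myr = per_myr,
         enrichment = enrichment, summary = summary, manifest = manifest),
    class = "orgflux_run"
  )
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

dated_node_table <- function(ds, n_dated_nodes) {
  internal <- ds$ages[ds$ages$node > n_tips(ds$species_tree) &
                        ds$ages$node != root_node(ds$species_tree), ,
                      drop = FALSE]
  internal <- internal[internal$age_my < ds$config$root_age, , drop = FALSE]
  if (nrow(internal) > n_dated_nodes) {
    internal <- internal[order(internal$age_my, decreasing = TRUE), ,
                         drop = FALSE][seq_len(n_dated_nodes), , drop = FALSE]
  }
  internal
}

#' @export
print.orgflux_run <- function(x, ...) {
  s <- x$summary
  cat("<orgflux_run>", s$n_orthogroups, "orthogroups,", s$n_species,
      "species\n")
  cat(sprintf("  retained events: %d (%d gains, %d losses)\n",
              s$n_events, s$n_gains, s$n_losses))
  if (!is.na(s$freq_dup)) {
    cat(sprintf("  child-branch change: %.1f%% after duplication vs %.1f%% after speciation (hypergeometric p = %.3g)\n",
                100 * s$freq_dup, 100 * s$freq_spec, s$dup_hypergeom_p))
  }
  if (!is.na(s$rate_mc_p)) {
    cat(sprintf("  normalized-rate elevation on change branches: t p = %.3g, Monte Carlo p = %.3g\n",
                s$rate_t_p, s$rate_mc_p))
  }
  invisible(x)
}

#' @method glance orgflux_run
#' @export
glance.orgflux_run <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
  }
  ev <- run$events
  if (nrow(ev)) {
    flat <- tidyr::unnest(ev, "assignment")
    w(flat, "events")
  } else {
    w(dplyr::select(ev, -"assignment"), "events")
  }
  w(run$tallies, "tallies")
  w(run$rates, "rates")
  w(run$dup_records, "duplication_nodes")
  if (!is.null(run$enrichment)) w(run$enrichment, "enrichment")
  if (nrow(run$per_myr)) w(run$per_myr, "per_myr_rates")
  write_newick(run$data$species_tree,
               file.path(outdir, "species_tree.nwk"))
  jsonlite::write_json(
    c(run$manifest, list(summary = run$summary)),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(outdir)
}
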