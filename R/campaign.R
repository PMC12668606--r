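# Batch-based campaign orchestration: split a design campaign into
# end-to-end instances over pluggable stages (generate -> graft/filter ->
# design sequences -> score -> evaluate), keep live score bookkeeping, and
# stop once the requested number of hits is reached.

#' Build a stage contract
#'
#' The three pluggable generative stages of the pipeline. Each must be pure
#' given its seed arguments. Real GPU tools plug in through this surface;
#' [mock_stages()] provides deterministic synthetic implementations.
#'
#' @param backbone_generator function(n, length_range, seed) -> list of
#'   `complex_model`
#' @param sequence_designer function(model, n_seq, seed) -> character vector
#'   of sequences
#' @param scorer function(model, sequence) -> `confidence_bundle`
#' @return a `stage_contract`
#' @export
stage_contract <- function(backbone_generator, sequence_designer, scorer) {
  stopifnot(is.function(backbone_generator), is.function(sequence_designer),
            is.function(scorer))
  structure(list(backbone_generator = backbone_generator,
                 sequence_designer = sequence_designer, scorer = scorer),
            class = "stage_contract")
}

#' Build a campaign configuration
#'
#' @param target_hits stop once this many hits have accumulated
#' @param batch_size designs per batch instance
#' @param length_range inclusive `c(min, max)` binder length, residues
#' @param seqs_per_backbone sequences designed per surviving backbone
#' @param strategy "standard", "partial_diffusion" or "sequence_diversity"
#' @param thresholds a `threshold_set` for hit calling
#' @param max_batches safety cap on total batches
#' @param seed campaign seed; per-batch seeds derive from it via
#'   [derive_seed()]
#' @param pd_noise partial-diffusion white-noise sd, Angstrom
#' @param clash_cutoff,long_helix_min filter parameters
#' @param output_dir if non-NULL, Scoring_Stats.csv is appended there after
#'   every batch
#' @return a `campaign_config`
#' @export
campaign_config <- function(target_hits, batch_size = 10,
                            length_range = c(65, 155),
                            seqs_per_backbone = 1,
                            strategy = c("standard", "partial_diffusion",
                                         "sequence_diversity"),
                            thresholds = default_thresholds(),
                            max_batches = 100, seed = 1, pd_noise = 0.5,
                            clash_cutoff = 0.5, long_helix_min = 40,
                            output_dir = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(batch_size >= 1, target_hits >= 0,
            length_range[1] <= length_range[2], max_batches >= 1)
  structure(list(target_hits = target_hits, batch_size = batch_size,
                 length_range = length_range,
                 seqs_per_backbone = seqs_per_backbone, strategy = strategy,
                 thresholds = thresholds, max_batches = max_batches,
                 seed = seed, pd_noise = pd_noise,
                 clash_cutoff = clash_cutoff,
                 long_helix_min = long_helix_min, output_dir = output_dir),
            class = "campaign_config")
}

#' Read a campaign configuration from JSON
#'
#' @param path JSON file with fields named as in [campaign_config()]
#'   (thresholds as an array of `{name, orientation, threshold, enabled}`)
#' @return a `campaign_config`
#' @export
read_campaign_config <- function(path) {
  js <- jsonlite::fromJSON(path)
  th <- if (!is.null(js$thresholds)) threshold_set(as.data.frame(js$thresholds))
        else default_thresholds()
  campaign_config(
    target_hits = js$target_hits,
    batch_size = js$batch_size %||% 10,
    length_range = js$length_range %||% c(65, 155),
    seqs_per_backbone = js$seqs_per_backbone %||% 1,
    strategy = js$strategy %||% "standard",
    thresholds = th,
    max_batches = js$max_batches %||% 100,
    seed = js$seed %||% 1,
    pd_noise = js$pd_noise %||% 0.5,
    output_dir = js$output_dir)
}

#' Resolve the effective stage plan for a strategy
#'
#' Standard campaigns use the stages as given (any reference is ignored).
#' Partial diffusion replaces backbone generation with white-noise
#' perturbation of a validated reference backbone (binder coordinates only;
#' the target stays fixed). Sequence diversity skips backbone generation
#' entirely: each batch scores `batch_size` sequences on the single fixed
#' reference backbone.
#'
#' @param config a `campaign_config`
#' @param stages a `stage_contract`
#' @param reference a validated `complex_model` (required for the two
#'   refinement strategies)
#' @return a `stage_contract` implementing the strategy
#' @export
strategy_dispatch <- function(config, stages, reference = NULL) {
  if (config$strategy == "standard") return(stages)
  if (is.null(reference)) {
    stop("strategy '", config$strategy, "' requires a reference model",
         call. = FALSE)
  }
  if (config$strategy == "partial_diffusion") {
    gen <- function(n, length_range, seed) {
      lapply(seq_len(n), function(i) {
        m <- reference
        b <- chain_atoms(m, m$binder_chain)
        b <- perturb_backbone(b, config$pd_noise,
                              seed = derive_seed(seed, i))
        m$atoms[m$atoms$chain == m$binder_chain, c("x", "y", "z")] <-
          b[, c("x", "y", "z")]
        m
      })
    }
    return(stage_contract(gen, stages$sequence_designer, stages$scorer))
  }
  # sequence_diversity: one fixed backbone per batch, many sequences
  gen <- function(n, length_range, seed) list(reference)
  stage_contract(gen, stages$sequence_designer, stages$scorer)
}

# score one model+sequence into a record
score_design <- function(model, sequence, bundle, design_id, batch_id,
                         config) {
  metrics <- list(plddt_binder = plddt_binder(bundle, model$binder_chain),
                  pae_interaction = pae_interaction(bundle,
                                                    model$binder_chain))
  iface <- interface_residues(model)
  metrics$cutre <- if (length(iface$target_residues) &&
                       length(iface$binder_residues)) {
    cutre(bundle, iface)
  } else NA_real_
  score_record(design_id, batch_id, metrics,
               binder_length = n_residues(model, model$binder_chain),
               strategy = config$strategy, thresholds = config$thresholds)
}

#' Run one batch end to end
#'
#' Generates (or perturbs) backbones, applies the clash and topology
#' filters -- rejected designs are recorded with their reason and never
#' scored -- then designs sequences for the survivors and scores each into
#' a `score_record`. The per-batch seed derives deterministically from
#' `(config$seed, batch_index)`, so a batch reproduces exactly regardless
#' of dispatch order.
#'
#' @param config a `campaign_config`
#' @param stages a `stage_contract` (already strategy-dispatched)
#' @param batch_index zero-based batch index
#' @return list of `score_record` (scored and filtered-out designs)
#' @export
run_batch <- function(config, stages, batch_index) {
  stopifnot(batch_index >= 0)
  seed_b <- derive_seed(config$seed, batch_index)
  batch_id <- sprintf("batch%04d", batch_index)
  n_backbones <- if (config$strategy == "sequence_diversity") 1L
                 else config$batch_size
  n_seq <- if (config$strategy == "sequence_diversity") config$batch_size
           else config$seqs_per_backbone
  models <- stages$backbone_generator(n_backbones, config$length_range,
                                      seed_b)
  records <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    attr(m, "design_ordinal") <- batch_index * n_backbones + (i - 1L)
    fl <- backbone_filter(m, config$clash_cutoff, config$long_helix_min)
    if (!fl$passes) {
      records[[length(records) + 1L]] <- score_record(
        sprintf("%s_d%03d", batch_id, i - 1L), batch_id, list(),
        binder_length = n_residues(m, m$binder_chain),
        topology = if (!is.null(fl$topology)) fl$topology$klass else "",
        filter_reason = fl$reason, strategy = config$strategy,
        thresholds = config$thresholds)
      next
    }
    seqs <- stages$sequence_designer(m, n_seq, derive_seed(seed_b, i))
    for (s in seq_along(seqs)) {
      bundle <- stages$scorer(m, seqs[s])
      rec <- score_design(m, seqs[s], bundle,
                          sprintf("%s_d%03d_s%02d", batch_id, i - 1L, s - 1L),
                          batch_id, config)
      rec$topology <- fl$topology$klass
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}

#' Run a campaign until the hit target is reached
#'
#' Batches are dispatched in waves of at most `parallel_instances`; after a
#' wave completes, the cumulative hit count is re-evaluated and no new wave
#' starts once `target_hits` is reached (in-flight batches of the final
#' wave are finished and counted, so the final tally may overshoot). A
#' zero-hit-rate stall terminates at `max_batches` with status
#' `"exhausted"`. When `config$output_dir` is set, records are appended to
#' `Scoring_Stats.csv` after every batch.
#'
#' @param config a `campaign_config`
#' @param stages a `stage_contract`
#' @param parallel_instances concurrent batch workers (waves)
#' @param reference reference model for refinement strategies
#' @return a `campaign_state`: counters, status, per-instance progress and
#'   all records (sorted by batch, design)
#' @export
run_campaign <- function(config, stages, parallel_instances = 1,
                         reference = NULL) {
  stopifnot(parallel_instances >= 1)
  stages <- strategy_dispatch(config, stages, reference)
  csv <- if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(config$output_dir, "Scoring_Stats.csv")
  } else NULL

  state <- list(batches_done = 0L, designs_generated = 0L,
                designs_scored = 0L, designs_filtered_out = 0L, hits = 0L,
                per_instance_status = list(), status = "running",
                records = list())
  class(state) <- "campaign_state"
  if (config$target_hits == 0L) { state$status <- "completed"; return(state) }

  next_batch <- 0L
  while (state$hits < config$target_hits &&
         state$batches_done < config$max_batches) {
    wave <- seq.int(next_batch,
                    length.out = min(parallel_instances,
                                     config$max_batches - state$batches_done))
    for (b in wave) {
      inst <- sprintf("instance%02d", b %% parallel_instances)
      recs <- tryCatch(run_batch(config, stages, b), error = function(e) e)
      if (inherits(recs, "error")) {
        state$per_instance_status[[inst]] <-
          sprintf("batch %d failed: %s", b, conditionMessage(recs))
        state$batches_done <- state$batches_done + 1L
        next
      }
      filtered <- vapply(recs, function(r) nzchar(r$filter_reason), logical(1))
      hits <- vapply(recs, function(r) isTRUE(r$is_hit), logical(1))
      state$designs_generated <- state$designs_generated + length(recs)
      state$designs_filtered_out <- state$designs_filtered_out + sum(filtered)
      state$designs_scored <- state$designs_scored + sum(!filtered)
      state$hits <- state$hits + sum(hits)
      state$batches_done <- state$batches_done + 1L
      state$records <- c(state$records, recs)
      state$per_instance_status[[inst]] <-
        sprintf("batch %d done (%d scored, %d hits)", b, sum(!filtered),
                sum(hits))
      if (!is.null(csv)) append_scores(csv, recs)
    }
    next_batch <- next_batch + length(wave)
  }
  state$status <- if (state$hits >= config$target_hits) "completed"
                  else "exhausted"
  # canonical order regardless of dispatch: by (batch, design id)
  ord <- order(vapply(state$records, function(r) r$batch_id, ""),
               vapply(state$records, function(r) r$design_id, ""))
  state$records <- state$records[ord]
  state
}

#' @export
print.campaign_state <- function(x, ...) {
  cat("<campaign_state> status:", x$status, "| batches:", x$batches_done,
      "| scored:", x$designs_scored, "| filtered:", x$designs_filtered_out,
      "| hits:", x$hits, "\n")
  invisible(x)
}

#' Summarize a campaign
#'
#' Per-batch and cumulative counts, the hit rate with its binomial standard
#' error, and the filter-rejection breakdown by reason; serializable to
#' JSON for any dashboard front-end.
#'
#' @param state a `campaign_state` from [run_campaign()]
#' @param records optionally override the record list
#' @return a list (JSON-ready)
#' @export
campaign_summary <- function(state, records = state$records) {
  n_scored <- state$designs_scored
  hit_rate <- if (n_scored > 0) state$hits / n_scored else 0
  se <- if (n_scored > 0) sqrt(hit_rate * (1 - hit_rate) / n_scored) else 0
  filtered <- Filter(function(r) nzchar(r$filter_reason), records)
  reasons <- table(vapply(filtered, function(r) r$filter_reason, ""))
  per_batch <- lapply(split(records,
                            vapply(records, function(r) r$batch_id, "")),
                      function(rs) {
                        list(n = length(rs),
                             scored = sum(!vapply(rs, function(r)
                               nzchar(r$filter_reason), logical(1))),
                             hits = sum(vapply(rs, function(r)
                               isTRUE(r$is_hit), logical(1))))
                      })
  list(status = state$status, batches_done = state$batches_done,
       designs_generated = state$designs_generated,
       designs_scored = n_scored,
       designs_filtered_out = state$designs_filtered_out,
       hits = state$hits, hit_rate = hit_rate, hit_rate_se = se,
       rejection_reasons = as.list(reasons), per_batch = per_batch,
       per_instance_status = state$per_instance_status)
}
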