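#' Assemble and validate a pipeline configuration
#'
#' @param posts Path to the posts file (JSONL or TSV).
#' @param aliases Path to the drug alias table.
#' @param lexicon Path to the expanded lexicon file.
#' @param target_drugs Character vector of target drug (or class) ids.
#' @param comparison_drugs Character vector of comparison drug ids; must be
#'   disjoint from `target_drugs`.
#' @param out_dir Output directory for intermediate tables and the manifest.
#' @param model Path to a serialized tagger (`write_tagger()`); optional when
#'   `gold_spans` is given.
#' @param gold_spans Optional path to a standoff span file used instead of
#'   tagging (gold-bypass mode).
#' @param drug_classes Optional named list: class id -> member drug ids, whose
#'   corpora are merged before counting.
#' @param known_associations,manual_exclusions,literature_events Optional
#'   paths (see [read_known_associations()], [read_manual_exclusions()],
#'   [read_literature_events()]).
#' @param target_groups Reaction groups to score (default: all groups in the
#'   lexicon).
#' @param percentile Calibration percentile (default 95).
#' @param fixed_rule Fixed flagging threshold (default 1).
#' @param min_controls Minimum finite control PRRs for calibration
#'   (default 10).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(posts, aliases, lexicon, target_drugs,
                            comparison_drugs, out_dir,
                            model = NULL, gold_spans = NULL,
                            drug_classes = NULL,
                            known_associations = NULL,
                            manual_exclusions = NULL,
                            literature_events = NULL,
                            target_groups = NULL,
                            percentile = 95, fixed_rule = 1.0,
                            min_controls = 10L, seed = 1L) {
  overlap <- intersect(target_drugs, comparison_drugs)
  if (length(overlap) > 0) {
    stop_adr(sprintf("Drug(s) in both target and comparison sets: %s",
                     paste(overlap, collapse = ", ")),
             "adrsignal_validation_error")
  }
  if (is.null(model) && is.null(gold_spans)) {
    stop_adr("Provide either a tagger `model` or `gold_spans`.",
             "adrsignal_validation_error")
  }
  paths <- purrr::compact(list(posts = posts, aliases = aliases,
                               lexicon = lexicon, model = model,
                               gold_spans = gold_spans,
                               known_associations = known_associations,
                               manual_exclusions = manual_exclusions,
                               literature_events = literature_events))
  missing <- paths[!purrr::map_lgl(paths, file.exists)]
  if (length(missing) > 0) {
    stop_adr(sprintf("Configured path does not exist (%s): %s",
                     names(missing)[1], missing[[1]]),
             "adrsignal_validation_error")
  }
  structure(
    list(posts = posts, aliases = aliases, lexicon = lexicon,
         target_drugs = target_drugs, comparison_drugs = comparison_drugs,
         out_dir = out_dir, model = model, gold_spans = gold_spans,
         drug_classes = drug_classes,
         known_associations = known_associations,
         manual_exclusions = manual_exclusions,
         literature_events = literature_events,
         target_groups = target_groups,
         percentile = percentile, fixed_rule = fixed_rule,
         min_controls = min_controls, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (fld in c("target_drugs", "comparison_drugs", "target_groups")) {
    if (!is.null(y[[fld]])) y[[fld]] <- unlist(y[[fld]])
  }
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_adr(sprintf("Pipeline stage `%s` failed: %s", name,
                     conditionMessage(e)),
             "adrsignal_stage_error", stage = name)
  })
}

#' Run the full signal-detection pipeline
#'
#' Executes corpus building, mention extraction (tagger or gold bypass),
#' concept normalization, unique-user aggregation, PRR computation,
#' negative-control calibration, signal flagging and (when literature events
#' are configured) time-to-detection analysis. Every intermediate table is
#' written to `out_dir` as tab-separated text along with a YAML run manifest
#' recording the seed, package version and per-stage cardinalities. A rerun
#' with the same configuration reproduces identical outputs.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return An `adr_run` report: list with `signals` (flagged signal table),
#'   `controls`, `threshold`, `leads` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "adrsignal",
                   version = as.character(utils::packageVersion("adrsignal")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    rlang::inform(sprintf("[%s] %s", stage,
                          paste(names(list(...)), unlist(list(...)),
                                sep = "=", collapse = " ")))
  }

  posts <- run_stage("read_posts", read_posts(config$posts))
  aliases <- run_stage("read_aliases", read_drug_aliases(config$aliases))
  lexicon <- run_stage("read_lexicon", read_lexicon(config$lexicon))
  index <- run_stage("build_index", build_concept_index(lexicon))
  groups <- config$target_groups %||% sort(unique(lexicon$group_id))
  note("input", posts = nrow(posts), aliases = nrow(aliases),
       lexicon_entries = nrow(lexicon), groups = length(groups))

  # corpora per drug, then class merges
  all_drugs <- union(config$target_drugs, config$comparison_drugs)
  class_members <- unlist(config$drug_classes %||% list())
  corpus_drugs <- union(setdiff(all_drugs, names(config$drug_classes %||% list())),
                        class_members)
  corpora <- run_stage("build_corpora", {
    purrr::map(setNames(corpus_drugs, corpus_drugs), function(d) {
      al <- aliases$alias[aliases$drug_id == d]
      if (length(al) == 0) al <- tolower(d)
      build_drug_corpus(posts, compile_drug_matcher(al), d)
    })
  })
  for (cls in names(config$drug_classes %||% list())) {
    corpora[[cls]] <- merge_corpora(corpora[config$drug_classes[[cls]]], cls)
    corpora[config$drug_classes[[cls]]] <- NULL
  }
  note("corpus", n_corpora = length(corpora),
       total_posts = sum(purrr::map_int(corpora, nrow)))

  corpus_posts <- dplyr::bind_rows(purrr::map(corpora, tibble::as_tibble)) |>
    dplyr::distinct(.data$post_id, .keep_all = TRUE)

  spans <- run_stage("extract_mentions", {
    if (!is.null(config$gold_spans)) {
      sp <- read_spans(config$gold_spans)
      sp[sp$post_id %in% corpus_posts$post_id, ]
    } else {
      model <- read_tagger(config$model)
      tag_posts(corpus_posts, model)
    }
  })
  note("mentions", n_spans = nrow(spans),
       n_adr = sum(spans$label == "ADR"))

  normalized <- run_stage("normalize",
                          normalize_mentions(spans, index, labels = "ADR"))
  records <- run_stage("pair_records", {
    purrr::map(corpora, extract_pair_records, spans = normalized) |>
      dplyr::bind_rows()
  })
  note("pairs", n_records = nrow(records),
       n_users = dplyr::n_distinct(records$user_id))
  readr::write_tsv(records, file.path(config$out_dir, "pair_records.tsv"),
                   progress = FALSE)

  signals <- run_stage("prr", {
    purrr::map(config$target_drugs, function(d) {
      aggregate_counts(records, d, config$comparison_drugs, groups = groups) |>
        compute_prr()
    }) |> dplyr::bind_rows()
  })

  controls <- run_stage("controls", {
    known <- if (!is.null(config$known_associations))
      read_known_associations(config$known_associations) else NULL
    excl <- if (!is.null(config$manual_exclusions))
      read_manual_exclusions(config$manual_exclusions) else NULL
    ctrl_pairs <- build_negative_controls(config$comparison_drugs, groups,
                                          known, excl)
    ctrl_prr <- purrr::map(config$comparison_drugs, function(d) {
      aggregate_counts(records, d,
                       setdiff(config$comparison_drugs, d),
                       groups = groups) |>
        compute_prr()
    }) |> dplyr::bind_rows()
    dplyr::semi_join(ctrl_prr, ctrl_pairs, by = c("drug_id", "group_id"))
  })
  threshold <- run_stage("calibrate",
                         calibrate_threshold(controls$prr,
                                             percentile = config$percentile,
                                             min_n = config$min_controls))
  note("calibration", n_controls = nrow(controls),
       threshold = signif(threshold, 6))
  readr::write_tsv(controls, file.path(config$out_dir, "controls.tsv"),
                   progress = FALSE)

  signals <- run_stage("flag",
                       flag_signals(signals, threshold,
                                    fixed_rule = config$fixed_rule))
  readr::write_tsv(signals, file.path(config$out_dir, "signals.tsv"),
                   progress = FALSE)
  note("signals", n_pairs = nrow(signals), n_flagged = sum(signals$flagged))

  leads <- NULL
  if (!is.null(config$literature_events)) {
    leads <- run_stage("timeline", {
      lit <- read_literature_events(config$literature_events)
      detection_leads(records, lit)
    })
    readr::write_tsv(leads, file.path(config$out_dir, "leads.tsv"),
                     progress = FALSE)
    note("timeline", n_events = nrow(leads),
         mean_lead = mean(leads$lead_months, na.rm = TRUE))
  }

  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yml"))
  structure(list(signals = signals, controls = controls,
                 threshold = threshold, leads = leads, records = records,
                 manifest = manifest, config = config),
            class = "adr_run")
}

#' @export
print.adr_run <- function(x, ...) {
  cat("<adr_run> ", nrow(x$signals), " target pair(s), ",
      sum(x$signals$flagged), " flagged; threshold ",
      format(x$threshold, digits = 4), " over ", nrow(x$controls),
      " negative controls\n", sep = "")
  invisible(x)
}
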