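# Stage wrapper: any failure aborts with an error naming the stage.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a statistic table as UTF-8 TSV
#'
#' Header row always present; an empty table yields a header-only file.
#' List columns (word lists in detectability tallies) are collapsed with
#' `";"`. Detectability tallies are sorted by type frequency (genuine
#' word count) descending before writing.
#'
#' @param x Data frame (or an object with a data frame interpretation,
#'   e.g. a `detectability_tally`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
emit_table <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "detectability_tally") && nrow(df) > 0) {
    df <- df[order(-df$n_genuine, df$affix), , drop = FALSE]
  }
  for (cl in names(df)) {
    if (is.list(df[[cl]])) {
      df[[cl]] <- vapply(df[[cl]], paste, "", collapse = ";")
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes cross-reference, exposure statistics, affix-inventory
#' selection and the detectability analysis in order, writing one TSV per
#' statistic plus a flat key-value run manifest (config digest, seed,
#' input checksums, row counts). Identical configurations and inputs
#' produce byte-identical bundles.
#'
#' The configuration is a list (or a YAML file parsed into one) with
#' either a `simulate` block ([synth_config()] arguments, plus optional
#' `bands`/`presence_prob` for a multi-band corpus) or an `inputs` block
#' (`lexicon`, `annotations` paths and their dialects, optional
#' `reference` path and `channel`). Optional top-level fields:
#' `threshold` (commonness criterion, default 0.01), `freq_cutoff`
#' (default 50), `max_depth` (default 6).
#'
#' @param config List or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed objects (`joined`,
#'   `common`, `tally`, `stats`) and the manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("pipeline stage 'config' failed: file not found: ", config,
        call. = FALSE
      )
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(config_digest = config_digest(config))

  reference <- NULL
  if (!is.null(config$simulate)) {
    corpus <- run_stage("simulate", {
      sim <- config$simulate
      bands <- sim$bands
      presence <- sim$presence_prob
      sim$bands <- NULL
      sim$presence_prob <- NULL
      if (!is.null(sim$affix_specs) && !is.data.frame(sim$affix_specs)) {
        # YAML configs carry the affix table as parallel lists
        sim$affix_specs <- as.data.frame(sim$affix_specs,
          stringsAsFactors = FALSE
        )
      }
      cfg <- do.call(synth_config, sim)
      if (is.null(bands)) {
        generate_lexicon(cfg)
      } else {
        if (is.null(presence)) presence <- c(0.7, 0.8, 0.9)
        generate_multiband(cfg, bands = bands, presence_prob = presence)
      }
    })
    entries <- corpus$entries
    morph <- corpus$gold
    manifest["seed"] <- corpus$config$seed
    write_band_lexicon(entries, file.path(out_dir, "lexicon.tsv"),
      header_comments = paste("seed:", corpus$config$seed)
    )
    write_gold_annotations(corpus, file.path(out_dir, "gold.tsv"))
  } else {
    inputs <- config$inputs
    if (is.null(inputs$lexicon) || is.null(inputs$annotations)) {
      stop("pipeline stage 'inputs' failed: need `simulate` or ",
        "`inputs$lexicon` + `inputs$annotations`",
        call. = FALSE
      )
    }
    entries <- run_stage("read_lexicon", read_band_lexicon(
      inputs$lexicon,
      dialect = inputs$lexicon_dialect %||% "canonical"
    ))
    morph <- run_stage("read_annotations", read_morph_annotations(
      inputs$annotations,
      dialect = inputs$annotations_dialect %||% "morpholex"
    ))
    if (!is.null(inputs$reference)) {
      reference <- run_stage("read_reference", read_reference_lexicon(
        inputs$reference,
        channel = inputs$channel %||% "ALL"
      ))
    }
    for (f in c(inputs$lexicon, inputs$annotations, inputs$reference)) {
      manifest[paste0("md5_", basename(f))] <- unname(tools::md5sum(f))
    }
  }

  joined <- run_stage("crossref", cross_reference(entries, morph))
  manifest["n_words"] <- nrow(joined$words)
  manifest["n_matched"] <- joined$coverage[["matched"]]

  stats_out <- run_stage("stats", {
    res <- list()
    for (b in joined$bands) {
      res[[paste0("complexity_", b)]] <- complexity_summary(joined, b)
      res[[paste0("frequency_", b)]] <- frequency_band_table(joined, b)
      res[[paste0("dispersion_", b)]] <- dispersion_table(joined, b)
      sd <- structure_distribution(joined, b)
      res[[paste0("structure_", b)]] <- sd$categories
      if (!is.null(reference)) {
        res[[paste0("reference_gap_", b)]] <- reference_gap_summary(
          joined, reference, b,
          freq_cutoff = config$freq_cutoff %||% 50
        )
      }
    }
    res
  })

  common <- run_stage(
    "affixes",
    select_common_affixes(joined, threshold = config$threshold %||% 0.01)
  )
  tally_usage <- run_stage("affixes", tally_affix_usage(joined))

  tally <- run_stage("detect", run_detectability(
    joined, common,
    max_depth = config$max_depth %||% 6
  ))
  manifest["n_affixes"] <- length(common$prefixes) + length(common$suffixes)

  for (nm in names(stats_out)) {
    emit_table(stats_out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  emit_table(tally_usage, file.path(out_dir, "affix_usage.tsv"))
  emit_table(
    detectability_summary(tally),
    file.path(out_dir, "detectability_summary.tsv")
  )
  emit_table(tally, file.path(out_dir, "detectability_words.tsv"))

  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(
    paste0(names(manifest), "=", unname(manifest)),
    manifest_path
  )
  invisible(list(
    joined = joined, common = common, tally = tally,
    stats = stats_out, manifest = manifest_path
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
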