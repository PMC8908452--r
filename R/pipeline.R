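# Orchestration: run the whole analysis (from input files or from the
# synthetic generator), render the publication-style frequency tables, and write
# a reproducible JSON manifest.

#' Pipeline run configuration
#'
#' @param seed integer seed; required.
#' @param n_per_group individuals per group for simulated inputs.
#' @param alpha significance level for all tests.
#' @param cin_high CIN class boundary in percent (a mean CIN at or above it
#'   is "high").
#' @param ch_low,ch_high true-diversity class bounds: TD below `ch_low` is
#'   low CH, above `ch_high` high, otherwise intermediate.
#' @param karyotype_file,fish_file,metadata_file optional input TSV paths;
#'   when `NULL` the synthetic generator supplies the data.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param format `"tsv"` or `"md"` for rendered tables.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, n_per_group = 34L, alpha = 0.05, cin_high = 25,
                       ch_low = 1.5, ch_high = 2,
                       karyotype_file = NULL, fish_file = NULL,
                       metadata_file = NULL, out_dir = NULL,
                       format = c("tsv", "md")) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, cin_high > 0, ch_low > 0, ch_high > ch_low)
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 alpha = alpha, cin_high = cin_high,
                 ch_low = ch_low, ch_high = ch_high,
                 karyotype_file = karyotype_file, fish_file = fish_file,
                 metadata_file = metadata_file, out_dir = out_dir,
                 format = match.arg(format)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed", call. = FALSE)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

format_count_pct <- function(n, pct) {
  ifelse(n == 0, "0 (0)", sprintf("%d (%s)", n, formatC(pct, format = "fg")))
}

format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", formatC(p, digits = 4, format = "f"))
}

#' Render a carrier table in the published layout
#'
#' One row per category with `"carriers (pct)"` cells for each group and
#' the Fisher p-value, e.g. `"monosomies  32 (94.1)  13 (38.2)  <0.0001"`.
#' Empty categories render as `"0 (0)"`.
#'
#' @param ct a [carriers_table()] tibble.
#' @param format `"tsv"` or `"md"`.
#' @return character vector of table lines (including the header).
#' @export
render_carrier_table <- function(ct, format = c("tsv", "md")) {
  format <- match.arg(format)
  cells <- cbind(ct$category,
                 format_count_pct(ct$exposed_carriers, ct$pct_exposed),
                 format_count_pct(ct$unexposed_carriers, ct$pct_unexposed),
                 format_p(ct$p_two_sided))
  header <- c("category", "exposed n (%)", "unexposed n (%)", "p")
  render_rows(rbind(header, cells), format)
}

#' Render the paired per-individual event table
#'
#' Includes a grand-total row whose counts are the column sums and whose
#' percentages are recomputed from those sums.
#'
#' @param pt a [paired_event_table()] tibble.
#' @param exposed_total,unexposed_total group metaphase totals used for the
#'   total row's percentages.
#' @param format `"tsv"` or `"md"`.
#' @return character vector of table lines.
#' @export
render_paired_table <- function(pt, exposed_total, unexposed_total,
                                format = c("tsv", "md")) {
  format <- match.arg(format)
  header <- c("pair", "exposed n", "exposed %", "unexposed n",
              "unexposed %", "p")
  body <- cbind(pt$pair, pt$exposed_events,
                formatC(pt$pct_exposed, digits = 2, format = "f"),
                pt$unexposed_events,
                formatC(pt$pct_unexposed, digits = 2, format = "f"),
                format_p(pt$p_two_sided))
  tot_e <- sum(pt$exposed_events); tot_u <- sum(pt$unexposed_events)
  total <- c("Total", tot_e,
             formatC(round_half_up(100 * tot_e / exposed_total, 2),
                     digits = 2, format = "f"),
             tot_u,
             formatC(round_half_up(100 * tot_u / unexposed_total, 2),
                     digits = 2, format = "f"), "")
  render_rows(rbind(header, body, total), format)
}

render_rows <- function(rows, format) {
  if (format == "tsv")
    return(unname(apply(rows, 1L, paste, collapse = "\t")))
  lines <- apply(rows, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  append(lines, paste0("|", paste(rep("---", ncol(rows)), collapse = "|"), "|"),
         after = 1L)
}

#' Run the full biomonitoring analysis pipeline
#'
#' With no input files, a synthetic cohort (FISH counts, karyotypes and
#' metadata) is generated from the seed; with input files, they are read
#' and validated. The pipeline then computes per-individual tallies,
#' carrier and paired frequency tables with Fisher tests, clonality calls,
#' recurrent structural regions, CIN profiles, clonal-diversity indices,
#' group comparisons for CIN/SDI/TD, chromosome stability rankings per
#' group, and per-group correlation matrices, and (optionally) writes
#' rendered tables plus a deterministic JSON manifest to `out_dir`.
#'
#' @param config a [run_config()].
#' @return a `cinch_report` list with all computed tables and test results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  if (is.null(config$fish_file)) {
    cohort <- simulate_cohort(config$n_per_group, seed = config$seed)
    fish <- cohort$fish
    metadata <- cohort$metadata
    kary_e <- simulate_karyotypes(karyotype_rate_model("exposed"),
                                  n_individuals = config$n_per_group,
                                  seed = NULL,
                                  sexes = metadata$constitutional_sex[
                                    metadata$group == "exposed"],
                                  individual_prefix = "E")
    kary_u <- simulate_karyotypes(karyotype_rate_model("unexposed"),
                                  n_individuals = config$n_per_group,
                                  seed = NULL,
                                  sexes = metadata$constitutional_sex[
                                    metadata$group == "unexposed"],
                                  individual_prefix = "U")
    kary_tbl <- dplyr::bind_rows(kary_e, kary_u)
    karyotypes <- tibble::tibble(
      individual_id = kary_tbl$individual_id,
      metaphase_id = kary_tbl$metaphase_id,
      karyotype = kary_tbl$karyotype,
      record = mapply(parse_karyotype, kary_tbl$karyotype,
                      kary_tbl$individual_id, kary_tbl$metaphase_id,
                      SIMPLIFY = FALSE))
  } else {
    fish <- read_fish_counts(config$fish_file)
    metadata <- tibble::as_tibble(utils::read.delim(config$metadata_file,
                                                    sep = "\t"))
    karyotypes <- read_karyotypes(config$karyotype_file)
    cohort <- NULL
  }

  tallies <- tally_cohort(karyotypes, metadata)
  te <- tallies[tallies$group == "exposed", ]
  tu <- tallies[tallies$group == "unexposed", ]
  group_meta_totals <- c(exposed = sum(te$n_metaphases),
                         unexposed = sum(tu$n_metaphases))
  carriers <- carriers_table(te, tu)
  paired <- if (nrow(te) == nrow(tu))
    paired_event_table(te, tu, group_meta_totals[["exposed"]],
                       group_meta_totals[["unexposed"]])

  recs_by_ind <- split(karyotypes$record, karyotypes$individual_id)
  recurrent <- recurrent_regions(recs_by_ind, min_individuals = 2L)
  clonality <- dplyr::bind_rows(lapply(names(recs_by_ind), function(id) {
    sex <- metadata$constitutional_sex[metadata$individual_id == id][1]
    cc <- call_clonality(recs_by_ind[[id]], sex)
    if (nrow(cc)) cc$individual_id <- id
    cc
  }))

  cin <- cin_cohort(fish, cin_high = config$cin_high)
  div <- diversity_cohort(fish)
  fish_groups <- metadata$group[match(cin$summary$individual_id,
                                      metadata$individual_id)]
  cin_e <- cin$summary$mean_cin[fish_groups == "exposed"]
  cin_u <- cin$summary$mean_cin[fish_groups == "unexposed"]
  comparisons <- dplyr::bind_rows(
    cbind(variable = "cin", compare_groups(cin_e, cin_u, alpha = config$alpha)),
    cbind(variable = "sdi",
          compare_groups(div$sdi[fish_groups == "exposed"],
                         div$sdi[fish_groups == "unexposed"],
                         alpha = config$alpha)),
    cbind(variable = "td",
          compare_groups(div$td[fish_groups == "exposed"],
                         div$td[fish_groups == "unexposed"],
                         alpha = config$alpha)))

  stability <- lapply(c(exposed = "exposed", unexposed = "unexposed"),
                      function(g) chromosome_stability(
                        cin$summary[fish_groups == g, ]))

  correlations <- lapply(c(exposed = "exposed", unexposed = "unexposed"),
                         function(g) {
    keep <- fish_groups == g
    df <- data.frame(
      cin = cin$summary$mean_cin[keep],
      td = div$td[keep], sdi = div$sdi[keep],
      age = metadata$age[match(cin$summary$individual_id[keep],
                               metadata$individual_id)],
      sex = metadata$constitutional_sex[match(cin$summary$individual_id[keep],
                                              metadata$individual_id)])
    if (g == "exposed")
      df$exposure_months <- metadata$exposure_months[
        match(cin$summary$individual_id[keep], metadata$individual_id)]
    correlation_matrix(df)
  })

  report <- structure(list(
    config = config,
    metadata = metadata,
    tallies = tallies,
    group_metaphase_totals = group_meta_totals,
    carriers = carriers,
    paired = paired,
    recurrent_regions = recurrent,
    clonality = clonality,
    cin = cin$summary,
    diversity = div,
    comparisons = comparisons,
    stability = stability,
    correlations = correlations,
    truth = if (!is.null(cohort)) cohort$truth), class = "cinch_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.cinch_report <- function(x, ...) {
  cat("<cinch_report>\n")
  cat(sprintf("  %d individuals, %d + %d metaphases\n",
              nrow(x$metadata), x$group_metaphase_totals[["exposed"]],
              x$group_metaphase_totals[["unexposed"]]))
  cat(sprintf("  mean CIN: exposed %.2f%%, unexposed %.2f%%\n",
              mean(x$cin$mean_cin[x$metadata$group[
                match(x$cin$individual_id, x$metadata$individual_id)] == "exposed"]),
              mean(x$cin$mean_cin[x$metadata$group[
                match(x$cin$individual_id, x$metadata$individual_id)] == "unexposed"])))
  cat(sprintf("  %d group comparisons, %d carrier categories\n",
              nrow(x$comparisons), nrow(x$carriers)))
  invisible(x)
}

#' Write pipeline outputs and a reproducible manifest
#'
#' Writes the rendered carrier and paired tables, the per-individual tally,
#' CIN and diversity TSVs, and `manifest.json` recording configuration,
#' seed, package version, summary results and every gate trace. The
#' manifest contains no timestamps: rerunning with the same config and
#' seed reproduces it byte for byte.
#'
#' @param report a `cinch_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- report$config$format
  writeLines(render_carrier_table(report$carriers, fmt),
             file.path(out_dir, "carrier_table.txt"))
  if (!is.null(report$paired))
    writeLines(render_paired_table(report$paired,
                                   report$group_metaphase_totals[["exposed"]],
                                   report$group_metaphase_totals[["unexposed"]],
                                   fmt),
               file.path(out_dir, "paired_table.txt"))
  utils::write.table(report$tallies, file.path(out_dir, "tallies.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$cin, file.path(out_dir, "cin_profiles.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$diversity, file.path(out_dir, "diversity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  cfg <- report$config
  manifest <- list(
    package = "cinch",
    version = as.character(utils::packageVersion("cinch")),
    config = cfg[c("seed", "n_per_group", "alpha", "cin_high",
                   "ch_low", "ch_high", "format")],
    group_metaphase_totals = as.list(report$group_metaphase_totals),
    n_tests = nrow(report$comparisons) + nrow(report$carriers) +
      if (!is.null(report$paired)) nrow(report$paired) else 0L,
    comparisons = report$comparisons,
    carriers = report$carriers,
    stability = lapply(report$stability, function(s)
      list(ranking = s$ranking, test = s$test)),
    correlation_flagged = lapply(report$correlations, function(cm) {
      idx <- which(cm$flagged & upper.tri(cm$flagged), arr.ind = TRUE)
      data.frame(var1 = rownames(cm$r)[idx[, 1]],
                 var2 = colnames(cm$r)[idx[, 2]],
                 r = cm$r[idx])
    }))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
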