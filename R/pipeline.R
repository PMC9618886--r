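# Orchestration: read clone tables + metadata, filter productive, exclude
# tumor clones, compute metrics, compare groups, run clinical statistics,
# and emit TSV outputs plus a machine-readable JSON manifest. All outputs
# are deterministic functions of the config and inputs.

#' Pipeline configuration
#'
#' @param clone_tables character vector of clone-table paths; names (or file
#'   names before the first `_` or `.`) must match metadata `sample_id`s.
#' @param metadata path to the sample metadata TSV
#'   (see [read_sample_metadata()]).
#' @param output_dir directory for outputs (created if missing).
#' @param dialect `"airr"` or `"mixcr"`.
#' @param column_map optional column map for the MiXCR dialect.
#' @param criteria a [tumor_criteria()].
#' @param log_base `"e"` or `"2"` for entropy/clonality.
#' @param n_top top-clone cutoff (default 10).
#' @param alpha significance threshold for differential clones, in (0, 1).
#' @param adjust add BH-adjusted p-values to the differential table.
#' @param min_shared_samples sharing threshold (integer or `"all"`).
#' @param n_perm permutations for the global V-usage test.
#' @param seed integer seed for permutation draws.
#' @param strict abort when a TRB sample yields no tumor clone (default
#'   `FALSE`: warn and continue, the sample may genuinely lack a dominant
#'   clone under the chosen thresholds).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(clone_tables, metadata, output_dir,
                            dialect = c("airr", "mixcr"), column_map = NULL,
                            criteria = tumor_criteria(), log_base = c("e", "2"),
                            n_top = 10L, alpha = 0.05, adjust = FALSE,
                            min_shared_samples = 2L, n_perm = 1000L,
                            seed = 1L, strict = FALSE) {
  if (is.null(names(clone_tables)))
    names(clone_tables) <- sub("[_.].*$", "", basename(clone_tables))
  structure(
    list(clone_tables = clone_tables, metadata = metadata,
         output_dir = output_dir, dialect = match.arg(dialect),
         column_map = column_map, criteria = criteria,
         log_base = match.arg(log_base), n_top = as.integer(n_top),
         alpha = alpha, adjust = isTRUE(adjust),
         min_shared_samples = min_shared_samples, n_perm = as.integer(n_perm),
         seed = as.integer(seed), strict = isTRUE(strict)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the arguments of [pipeline_config()];
#' `tumor_criteria` may be given as a mapping with the argument names of
#' [tumor_criteria()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    tmerep_error(paste("config file not found:", path), "tmerep_io_error")
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    tmerep_error(paste("cannot parse config", path, ":", conditionMessage(e)),
                 "tmerep_config_error"))
  crit <- if (!is.null(y$tumor_criteria)) do.call(tumor_criteria, y$tumor_criteria)
          else tumor_criteria()
  args <- y[intersect(names(y), c("clone_tables", "metadata", "output_dir",
                                  "dialect", "column_map", "log_base", "n_top",
                                  "alpha", "adjust", "min_shared_samples",
                                  "n_perm", "seed", "strict"))]
  args$clone_tables <- unlist(args$clone_tables)
  args$criteria <- crit
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' @param cfg a `pipeline_config`.
#' @return character vector of problems, each prefixed with the offending
#'   field; empty when the pipeline can start.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(field, msg) sprintf("%s: %s", field, msg)
  if (length(cfg$clone_tables) == 0L)
    problems <- c(problems, add("clone_tables", "no clone tables given"))
  missing_files <- cfg$clone_tables[!file.exists(cfg$clone_tables)]
  if (length(missing_files))
    problems <- c(problems, add("clone_tables",
      paste("missing file(s):", paste(missing_files, collapse = ", "))))
  if (!file.exists(cfg$metadata))
    problems <- c(problems, add("metadata", paste("missing file:", cfg$metadata)))
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    problems <- c(problems, add("alpha", "must lie in (0, 1)"))
  if (!cfg$log_base %in% c("e", "2"))
    problems <- c(problems, add("log_base", "must be 'e' or '2'"))
  if (cfg$n_top < 1)
    problems <- c(problems, add("n_top", "must be >= 1"))
  if (!identical(cfg$min_shared_samples, "all") &&
      (!is.numeric(cfg$min_shared_samples) || cfg$min_shared_samples < 1))
    problems <- c(problems, add("min_shared_samples", "must be >= 1 or 'all'"))
  if (file.exists(cfg$metadata)) {
    md <- tryCatch(read_sample_metadata(cfg$metadata), error = function(e) NULL)
    if (is.null(md)) {
      problems <- c(problems, add("metadata", "cannot be parsed"))
    } else {
      bad_locus <- setdiff(unique(md$locus), c("TRB", "IGH"))
      if (length(bad_locus))
        problems <- c(problems, add("metadata",
          paste("unsupported locus:", paste(bad_locus, collapse = ", "))))
      absent <- setdiff(names(cfg$clone_tables), md$sample_id)
      if (length(absent))
        problems <- c(problems, add("clone_tables",
          paste("sample(s) not in metadata:", paste(absent, collapse = ", "))))
    }
  }
  problems
}

stage_run <- function(manifest, stage, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    manifest$stages[[stage]] <- list(status = "failed",
                                     error = conditionMessage(res))
    manifest$valid <- FALSE
    assign("manifest", manifest, envir = parent.frame())
    tmerep_error(sprintf("stage '%s' failed: %s", stage, conditionMessage(res)),
                 "tmerep_stage_error")
  }
  res
}

comparison_row <- function(type, locus, cmp) {
  data.frame(type = type, locus = locus, name = cmp$metric,
             n_case = cmp$n_a, n_control = cmp$n_b,
             median_case = cmp$median_a, median_control = cmp$median_b,
             statistic = cmp$statistic, p.value = cmp$p.value,
             direction = c(A = "case", B = "control", none = "none")[cmp$direction],
             method = cmp$method, stringsAsFactors = FALSE)
}

#' Run the full TME repertoire analysis
#'
#' Stages: validate config, read metadata and clone tables, filter to
#' productive rearrangements, identify and exclude the lymphoma clone (TRB
#' only), compute per-sample metrics, compare the two groups per metric and
#' per V family (plus a global usage test), detect shared and differential
#' CDR3s, and run the clinical statistics (Fisher tests on binary
#' covariates, Kaplan-Meier and log-rank on survival columns). Writes
#' `metrics.tsv`, `comparison.tsv`, `sharing.tsv`, `differential.tsv`,
#' `clinstats.tsv` and `manifest.json` into the output directory. Identical
#' config and inputs produce byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`metrics`,
#'   `comparison`, `sharing`, `differential`, `clinstats`, `manifest`) and
#'   output `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  problems <- validate_config(cfg)
  if (length(problems))
    tmerep_error(paste0("invalid configuration:\n  ",
                        paste(problems, collapse = "\n  ")),
                 "tmerep_config_error")
  if (!dir.exists(cfg$output_dir) &&
      !dir.create(cfg$output_dir, recursive = TRUE))
    tmerep_error(paste("cannot create output directory", cfg$output_dir),
                 "tmerep_io_error")

  manifest <- list(
    package = "tmerep",
    version = as.character(utils::packageVersion("tmerep")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum({
      tf <- tempfile(); saveRDS(cfg[setdiff(names(cfg), "output_dir")], tf,
                                version = 2); tf
    })),
    stages = list(), samples = list(), valid = TRUE
  )

  metadata <- stage_run(manifest, "read_metadata", read_sample_metadata(cfg$metadata))
  manifest$stages$read_metadata <- list(status = "ok", rows = nrow(metadata))

  reps <- stage_run(manifest, "read_clone_tables", {
    lapply(names(cfg$clone_tables), function(id) {
      row <- metadata[metadata$sample_id == id, , drop = FALSE][1, ]
      reader <- if (cfg$dialect == "airr") read_airr else
        function(p, ...) read_mixcr(p, column_map = cfg$column_map, ...)
      reader(cfg$clone_tables[[id]], sample_id = id, locus = row$locus)
    })
  })
  names(reps) <- names(cfg$clone_tables)
  manifest$stages$read_clone_tables <-
    list(status = "ok", samples = length(reps),
         total_clones = sum(vapply(reps, function(r) nrow(r$clones), 0)))

  tmes <- stage_run(manifest, "tme_construction", {
    lapply(reps, function(r) {
      prod <- filter_productive(r)
      tumor <- if (prod$locus == "TRB")
        identify_tumor_clones(prod, cfg$criteria)
      else prod$clones[0, , drop = FALSE]
      if (prod$locus == "TRB" && nrow(tumor) == 0L) {
        msg <- sprintf("sample '%s': no tumor clone met the calling criteria",
                       prod$sample_id)
        if (cfg$strict) tmerep_error(msg, "tmerep_notfound_error")
        warning(msg, call. = FALSE)
      }
      build_tme(prod, tumor)
    })
  })
  manifest$samples <- lapply(tmes, function(t) list(
    sample_id = t$sample_id, locus = t$locus,
    tumor_clones = t$tumor_clones$cdr3_nt,
    tumor_reads = t$tumor_reads, total_reads = t$total_reads,
    denominator = t$denominator, tme_clones = nrow(t$clones)))
  manifest$stages$tme_construction <- list(status = "ok", samples = length(tmes))

  loci <- unique(vapply(tmes, `[[`, "", "locus"))
  group_of <- stats::setNames(metadata$group, metadata$sample_id)

  rbind_fill <- function(dfs) {
    dfs <- Filter(Negate(is.null), dfs)
    if (!length(dfs)) return(NULL)
    cols <- unique(unlist(lapply(dfs, names)))
    do.call(rbind, lapply(dfs, function(d) {
      for (col in setdiff(cols, names(d))) d[[col]] <- if (is.character(d[[1]])) 0 else 0
      d[, cols, drop = FALSE]
    }))
  }

  metrics <- stage_run(manifest, "metrics", {
    rbind_fill(lapply(loci, function(lc) {
      sub <- tmes[vapply(tmes, function(t) t$locus == lc, TRUE)]
      metrics_table(sub, base = cfg$log_base, n_top = cfg$n_top)
    }))
  })
  manifest$stages$metrics <- list(status = "ok", rows = nrow(metrics))

  comparison <- stage_run(manifest, "comparison", {
    rows <- list()
    for (lc in loci) {
      sub <- tmes[vapply(tmes, function(t) t$locus == lc, TRUE)]
      grp <- group_of[vapply(sub, `[[`, "", "sample_id")]
      if (length(unique(grp)) != 2L) next
      m <- metrics[metrics$locus == lc, , drop = FALSE]
      is_case <- group_of[m$sample_id] == "case"
      for (met in c("richness", "entropy", "clonality", "top10_proportion")) {
        cmp <- compare_metric(m[[met]][is_case], m[[met]][!is_case], metric = met)
        rows[[length(rows) + 1L]] <- comparison_row("metric", lc, cmp)
      }
      usage <- lapply(sub, v_family_usage)
      vu <- compare_v_usage(usage[grp == "case"], usage[grp == "control"],
                            n_perm = cfg$n_perm, seed = cfg$seed)
      for (fam in names(vu$per_family))
        rows[[length(rows) + 1L]] <-
          comparison_row("v_family", lc, vu$per_family[[fam]])
      rows[[length(rows) + 1L]] <- data.frame(
        type = "v_usage_global", locus = lc, name = "global",
        n_case = sum(grp == "case"), n_control = sum(grp == "control"),
        median_case = NA_real_, median_control = NA_real_,
        statistic = vu$global$statistic, p.value = vu$global$p.value,
        direction = "none", method = sprintf("permutation(%d)", vu$global$n_perm),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  manifest$stages$comparison <- list(status = "ok", rows = nrow(comparison))

  sharing <- stage_run(manifest, "sharing", {
    do.call(rbind, lapply(loci, function(lc) {
      sub <- tmes[vapply(tmes, function(t) t$locus == lc, TRUE)]
      if (length(sub) < 2L) return(NULL)
      sh <- find_shared_clones(sub, min_samples = cfg$min_shared_samples)
      if (nrow(sh)) cbind(locus = lc, sh) else NULL
    }))
  })
  manifest$stages$sharing <-
    list(status = "ok", rows = if (is.null(sharing)) 0L else nrow(sharing))

  differential <- stage_run(manifest, "differential", {
    do.call(rbind, lapply(loci, function(lc) {
      sub <- tmes[vapply(tmes, function(t) t$locus == lc, TRUE)]
      grp <- group_of[vapply(sub, `[[`, "", "sample_id")]
      if (length(unique(grp)) != 2L) return(NULL)
      dc <- differential_clones(sub[grp == "case"], sub[grp == "control"],
                                alpha = cfg$alpha, adjust = cfg$adjust)
      if (nrow(dc)) cbind(locus = lc, dc) else NULL
    }))
  })
  manifest$stages$differential <-
    list(status = "ok", rows = if (is.null(differential)) 0L else nrow(differential))

  clinstats <- stage_run(manifest, "clinstats", {
    rows <- list()
    md1 <- metadata[!duplicated(metadata$sample_id), , drop = FALSE]
    is_case <- md1$group == "case"
    reserved <- c("sample_id", "locus", "group", "tumor_fraction",
                  "survival_time", "event")
    for (feat in setdiff(names(md1), reserved)) {
      v <- md1[[feat]]
      ok <- !is.na(v)
      if (!all(v[ok] %in% c(0, 1))) next
      tab <- matrix(c(sum(v[ok & is_case] == 1), sum(v[ok & is_case] == 0),
                      sum(v[ok & !is_case] == 1), sum(v[ok & !is_case] == 0)),
                    2, byrow = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "fisher_exact", name = feat,
        case_positive = tab[1, 1], case_total = sum(tab[1, ]),
        control_positive = tab[2, 1], control_total = sum(tab[2, ]),
        statistic = NA_real_, p.value = fisher_exact_2x2(tab),
        stringsAsFactors = FALSE)
    }
    if (all(c("survival_time", "event") %in% names(md1)) &&
        any(!is.na(md1$survival_time))) {
      sv <- md1[!is.na(md1$survival_time) & !is.na(md1$event), , drop = FALSE]
      for (g in c("case", "control")) {
        km <- km_fit(sv$survival_time[sv$group == g], sv$event[sv$group == g])
        rows[[length(rows) + 1L]] <- data.frame(
          test = "km_median", name = g,
          case_positive = NA_real_, case_total = km$n,
          control_positive = NA_real_, control_total = km$n_events,
          statistic = km$median, p.value = NA_real_, stringsAsFactors = FALSE)
      }
      lr <- logrank_test(sv$survival_time[sv$group == "case"],
                         sv$event[sv$group == "case"],
                         sv$survival_time[sv$group == "control"],
                         sv$event[sv$group == "control"])
      rows[[length(rows) + 1L]] <- data.frame(
        test = "logrank", name = "overall_survival",
        case_positive = NA_real_, case_total = sum(sv$group == "case"),
        control_positive = NA_real_, control_total = sum(sv$group == "control"),
        statistic = lr$statistic, p.value = lr$p.value, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  manifest$stages$clinstats <-
    list(status = "ok", rows = if (is.null(clinstats)) 0L else nrow(clinstats))

  write_tsv <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    if (is.null(df))
      df <- data.frame(note = sprintf("no rows produced for %s", name))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    metrics = write_tsv(metrics, "metrics.tsv"),
    comparison = write_tsv(comparison, "comparison.tsv"),
    sharing = write_tsv(sharing, "sharing.tsv"),
    differential = write_tsv(differential, "differential.tsv"),
    clinstats = write_tsv(clinstats, "clinstats.tsv")
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$manifest <- manifest_path

  invisible(list(metrics = metrics, comparison = comparison, sharing = sharing,
                 differential = differential, clinstats = clinstats,
                 manifest = manifest, paths = paths))
}
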