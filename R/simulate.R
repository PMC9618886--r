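# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: heavy-tailed (log-normal or power-law) clone abundance,
# a spiked dominant tumor clone in TRB, Dirichlet V-family usage, a
# cross-sample public-clone pool, a group effect on the abundance tail
# (inducing clonality/entropy differences), and a clinical sheet with binary
# features and censored exponential survival. Everything is driven by
# integer seeds derived from the config seed, so output is reproducible.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG")
)

DEFAULT_V_FAMILIES <- list(
  TRB = paste0("TRBV", c(2:7, 9:16, 18:20, 24, 25, 27:30)),
  IGH = paste0("IGHV", 1:7)
)

rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  g / sum(g)
}

# Integer read counts from normalized frequencies by largest-remainder
# rounding: totals are conserved exactly and the result is deterministic
# (ties go to the earlier clone).
largest_remainder <- function(freq, total) {
  exact <- freq * total
  counts <- floor(exact)
  rem <- exact - counts
  need <- round(total - sum(counts))
  if (need > 0) {
    top <- order(-rem, seq_along(rem))[seq_len(need)]
    counts[top] <- counts[top] + 1
  }
  counts
}

random_cdr3_aa <- function(n, mean_len, sd_len, locus) {
  len <- pmax(8L, round(stats::rnorm(n, mean_len, sd_len)))
  last <- if (locus == "TRB") "F" else "W"
  vapply(len, function(L)
    paste0("C", paste(sample(AA_ALPHABET, L - 2L, replace = TRUE),
                      collapse = ""), last), "")
}

# Back-generate nucleotide CDR3s from amino acids with a seeded codon
# choice, so amino-acid sharing and nucleotide identity can disagree.
aa_to_nt <- function(aa) {
  chars <- strsplit(aa, "")
  flat <- unlist(chars)
  n_codons <- lengths(CODON_TABLE)[flat]
  pick <- floor(stats::runif(length(flat)) * n_codons) + 1L
  codons <- unlist(CODON_TABLE, use.names = FALSE)
  offset <- c(0L, cumsum(lengths(CODON_TABLE)))
  names(offset) <- c(names(CODON_TABLE), "END")
  flat_nt <- codons[offset[flat] + pick]
  vapply(split(flat_nt, rep(seq_along(aa), lengths(chars))),
         paste, "", collapse = "")
}

random_v_calls <- function(fams) {
  paste0(fams, "-", sample.int(9L, length(fams), replace = TRUE),
         "*0", sample.int(2L, length(fams), replace = TRUE))
}

#' Simulation configuration
#'
#' The default configuration emulates the study design the package targets:
#' 6 cases vs 12 controls at the TRB locus, roughly 1,000-2,000 clones and
#' 1e5 reads per sample, log-normal clone abundance (`sigma` 1.7 for
#' controls) with an additive `sigma_shift` of 0.5 in cases — which
#' reproduces clonality scores near 0.19 (controls) and 0.31 (cases) — a
#' dominant tumor clone holding 20% of TRB reads, Dirichlet V-family usage,
#' and a public-clone pool shared across samples. Survival is exponential
#' with group-specific hazards (median ~5 months in cases; most controls
#' censored alive) under uniform censoring.
#'
#' @param n_cases,n_controls samples per group.
#' @param locus `"TRB"` or `"IGH"`.
#' @param clones_per_sample single integer or length-2 range; the clone
#'   count per sample is drawn uniformly from the range.
#' @param abundance `"lognormal"` or `"powerlaw"`.
#' @param sigma log-normal sd of log clone weights (baseline, controls).
#' @param alpha_powerlaw Pareto tail exponent when `abundance = "powerlaw"`.
#' @param sigma_shift additive group effect on `sigma` (or on
#'   `1/alpha_powerlaw`'s scale for power-law) applied to cases.
#' @param total_reads reads per sample.
#' @param tumor_fraction read fraction of the spiked tumor clone (TRB only;
#'   0 disables; must be < 1).
#' @param v_families character vector of V families (default per locus).
#' @param v_concentration Dirichlet concentration (scalar or per family).
#' @param public_pool list with `size`, `p_case`, `p_control` (per-sample
#'   inclusion probabilities) and `freq_scale` (weight multiplier).
#' @param cdr3_length_mean,cdr3_length_sd amino-acid CDR3 length model.
#' @param hazard_case,hazard_control exponential event hazards (per month).
#' @param censor_range uniform censoring window in months.
#' @param features named list of length-2 vectors `c(p_case, p_control)` of
#'   binary clinical-feature probabilities.
#' @param seed integer master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 6L, n_controls = 12L, locus = c("TRB", "IGH"),
                       clones_per_sample = c(900L, 2200L),
                       abundance = c("lognormal", "powerlaw"),
                       sigma = 1.7, alpha_powerlaw = 2.0, sigma_shift = 0.5,
                       total_reads = 1e5, tumor_fraction = 0.2,
                       v_families = NULL, v_concentration = 3,
                       public_pool = list(size = 25L, p_case = 0.5,
                                          p_control = 0.5, freq_scale = 1),
                       cdr3_length_mean = 14.5, cdr3_length_sd = 1.3,
                       hazard_case = log(2) / 5, hazard_control = log(2) / 36,
                       censor_range = c(6, 60),
                       features = list(edema = c(1.0, 0.3),
                                       serous_effusion = c(1.0, 0.3),
                                       high_ebv_dna = c(1.0, 0.0)),
                       seed = 42L) {
  locus <- match.arg(locus)
  abundance <- match.arg(abundance)
  cfg_err <- function(msg) tmerep_error(msg, "tmerep_config_error")
  if (tumor_fraction < 0 || tumor_fraction >= 1)
    cfg_err("tumor_fraction must lie in [0, 1)")
  if (any(clones_per_sample < 2)) cfg_err("clones_per_sample must be >= 2")
  if (sigma <= 0) cfg_err("sigma must be positive")
  for (p in c(public_pool$p_case, public_pool$p_control))
    if (p < 0 || p > 1) cfg_err("public-pool inclusion probabilities must lie in [0, 1]")
  if (is.null(v_families)) v_families <- DEFAULT_V_FAMILIES[[locus]]
  if (length(v_concentration) == 1L)
    v_concentration <- rep(v_concentration, length(v_families))
  if (length(v_concentration) != length(v_families))
    cfg_err("v_concentration must be scalar or one value per V family")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         locus = locus, clones_per_sample = as.integer(clones_per_sample),
         abundance = abundance, sigma = sigma,
         alpha_powerlaw = alpha_powerlaw, sigma_shift = sigma_shift,
         total_reads = total_reads, tumor_fraction = tumor_fraction,
         v_families = v_families, v_concentration = v_concentration,
         public_pool = public_pool,
         cdr3_length_mean = cdr3_length_mean, cdr3_length_sd = cdr3_length_sd,
         hazard_case = hazard_case, hazard_control = hazard_control,
         censor_range = censor_range, features = features,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sample_seed <- function(cfg, sample_index, stream = 0L) {
  (cfg$seed %% 100000L) * 20011L + sample_index * 7919L + stream * 104729L
}

sample_ids_for <- function(cfg) {
  c(sprintf("case%02d", seq_len(cfg$n_cases)),
    sprintf("ctrl%02d", seq_len(cfg$n_controls)))
}

# The public pool is a cohort-level object, fixed by the config seed alone:
# CDR3s, V calls and a characteristic base weight per pool clone (so a
# public clone has a correlated size across the samples that carry it).
public_pool_clones <- function(cfg) {
  size <- cfg$public_pool$size
  if (is.null(size) || size == 0L)
    return(NULL)
  set.seed(sample_seed(cfg, 0L, stream = 1L))
  aa <- random_cdr3_aa(size, cfg$cdr3_length_mean, cfg$cdr3_length_sd, cfg$locus)
  fams <- sample(cfg$v_families, size, replace = TRUE,
                 prob = rdirichlet1(cfg$v_concentration))
  list(cdr3_aa = aa, cdr3_nt = aa_to_nt(aa), v_call = random_v_calls(fams),
       j_call = rep(if (cfg$locus == "TRB") "TRBJ2-1*01" else "IGHJ4*02", size),
       base_weight = stats::rlnorm(size, 0, cfg$sigma))
}

draw_weights <- function(cfg, n, sigma_eff) {
  if (cfg$abundance == "lognormal") {
    stats::rlnorm(n, 0, sigma_eff)
  } else {
    alpha <- max(1.05, cfg$alpha_powerlaw - (sigma_eff - cfg$sigma))
    stats::runif(n)^(-1 / (alpha - 1))
  }
}

#' Simulate one repertoire
#'
#' Clone weights are drawn from the configured abundance model, public-pool
#' clones are inserted with the group's inclusion probability, the tumor
#' clone (TRB only) is spiked at exactly `tumor_fraction` of the pre-rounding
#' mass, and read counts are produced by largest-remainder rounding of the
#' normalized weights (total reads conserved exactly; clones rounded to zero
#' reads are dropped and the realized count is recorded in the ground
#' truth).
#'
#' @param cfg a [sim_config()].
#' @param sample_index 1-based index; indices `1..n_cases` are cases.
#' @return list with `repertoire` (a [repertoire]) and `truth` (list:
#'   sample_id, group, sigma, clones configured/realized, tumor clone id and
#'   realized read fraction, public-pool members present).
#' @export
simulate_repertoire <- function(cfg, sample_index) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sample_ids_for(cfg)
  stopifnot(sample_index >= 1, sample_index <= length(ids))
  id <- ids[sample_index]
  group <- if (sample_index <= cfg$n_cases) "case" else "control"
  sigma_eff <- cfg$sigma + if (group == "case") cfg$sigma_shift else 0
  pool <- public_pool_clones(cfg)

  set.seed(sample_seed(cfg, sample_index, stream = 2L))
  n_bg <- if (length(cfg$clones_per_sample) == 2L)
    sample(cfg$clones_per_sample[1]:cfg$clones_per_sample[2], 1L)
  else cfg$clones_per_sample[1]

  w <- draw_weights(cfg, n_bg, sigma_eff)
  aa <- random_cdr3_aa(n_bg, cfg$cdr3_length_mean, cfg$cdr3_length_sd, cfg$locus)
  fam_probs <- rdirichlet1(cfg$v_concentration)
  fams <- sample(cfg$v_families, n_bg, replace = TRUE, prob = fam_probs)
  clones <- data.frame(
    cdr3_aa = aa, cdr3_nt = aa_to_nt(aa),
    v_call = random_v_calls(fams),
    j_call = if (cfg$locus == "TRB") "TRBJ2-1*01" else "IGHJ4*02",
    weight = w, origin = "background", stringsAsFactors = FALSE
  )

  if (!is.null(pool)) {
    p_inc <- if (group == "case") cfg$public_pool$p_case else cfg$public_pool$p_control
    inc <- stats::runif(length(pool$cdr3_aa)) < p_inc
    if (any(inc)) {
      jitter <- stats::rlnorm(sum(inc), 0, 0.5)
      scale <- if (is.null(cfg$public_pool$freq_scale)) 1 else cfg$public_pool$freq_scale
      clones <- rbind(clones, data.frame(
        cdr3_aa = pool$cdr3_aa[inc], cdr3_nt = pool$cdr3_nt[inc],
        v_call = pool$v_call[inc], j_call = pool$j_call[inc],
        weight = scale * pool$base_weight[inc] * jitter,
        origin = "public", stringsAsFactors = FALSE
      ))
    }
  }

  tumor_id <- NA_character_
  if (cfg$locus == "TRB" && cfg$tumor_fraction > 0) {
    t_aa <- random_cdr3_aa(1L, cfg$cdr3_length_mean, cfg$cdr3_length_sd, cfg$locus)
    clones <- rbind(clones, data.frame(
      cdr3_aa = t_aa, cdr3_nt = aa_to_nt(t_aa),
      v_call = random_v_calls(sample(cfg$v_families, 1L)),
      j_call = "TRBJ2-1*01",
      weight = cfg$tumor_fraction / (1 - cfg$tumor_fraction) * sum(clones$weight),
      origin = "tumor", stringsAsFactors = FALSE
    ))
  }

  freq <- clones$weight / sum(clones$weight)
  counts <- largest_remainder(freq, cfg$total_reads)
  keep <- counts > 0
  clones <- clones[keep, , drop = FALSE]
  counts <- counts[keep]
  clones$clone_id <- sprintf("%s_%s_%05d", id, tolower(clones$origin),
                             seq_len(nrow(clones)))
  tab <- data.frame(
    clone_id = clones$clone_id, cdr3_nt = clones$cdr3_nt,
    cdr3_aa = clones$cdr3_aa, v_call = clones$v_call, j_call = clones$j_call,
    read_count = counts, productive = TRUE, stringsAsFactors = FALSE
  )
  rep <- repertoire(tab, sample_id = id, locus = cfg$locus)

  is_tumor <- clones$origin == "tumor"
  truth <- list(
    sample_id = id, group = group, sigma = sigma_eff,
    n_clones_configured = n_bg,
    n_clones_realized = nrow(rep$clones),
    tumor_clone_id = if (any(is_tumor)) clones$clone_id[is_tumor] else NA_character_,
    tumor_cdr3_nt = if (any(is_tumor)) clones$cdr3_nt[is_tumor] else NA_character_,
    tumor_fraction_target = if (cfg$locus == "TRB") cfg$tumor_fraction else 0,
    tumor_read_fraction = sum(counts[is_tumor]) / cfg$total_reads,
    public_members = clones$cdr3_aa[clones$origin == "public"],
    total_reads = sum(counts)
  )
  list(repertoire = rep, truth = truth)
}

#' Simulate a full two-group cohort
#'
#' Generates every sample's repertoire plus a clinical metadata sheet:
#' group label, the realized tumor read fraction, exponential survival times
#' with group-specific hazards under uniform censoring, and binary clinical
#' features drawn with per-group probabilities. With `dir` given, writes one
#' AIRR Rearrangement TSV per sample, `metadata.tsv` and
#' `ground_truth.json`; the clone tables round-trip through [read_airr()].
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory (created if missing).
#' @param clone_tables generate the repertoires (default `TRUE`); `FALSE`
#'   emits the clinical sheet only, for survival/feature studies.
#' @return (invisibly when writing) list with `repertoires` (named list),
#'   `metadata` (data.frame), `truth` (per-sample list) and, when `dir` is
#'   given, `paths`.
#' @export
simulate_cohort <- function(cfg, dir = NULL, clone_tables = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sample_ids_for(cfg)
  if (clone_tables) {
    sims <- lapply(seq_along(ids), function(i) simulate_repertoire(cfg, i))
    reps <- lapply(sims, `[[`, "repertoire")
    truth <- lapply(sims, `[[`, "truth")
    names(reps) <- names(truth) <- ids
  } else {
    reps <- NULL
    truth <- lapply(seq_along(ids), function(i) list(
      sample_id = ids[i],
      group = if (i <= cfg$n_cases) "case" else "control",
      tumor_read_fraction = NA_real_))
    names(truth) <- ids
  }

  set.seed(sample_seed(cfg, 0L, stream = 3L))
  group <- vapply(truth, `[[`, "", "group")
  hazard <- ifelse(group == "case", cfg$hazard_case, cfg$hazard_control)
  t_event <- stats::rexp(length(ids), rate = hazard)
  t_censor <- stats::runif(length(ids), cfg$censor_range[1], cfg$censor_range[2])
  metadata <- data.frame(
    sample_id = ids, locus = cfg$locus, group = group,
    tumor_fraction = vapply(truth, `[[`, 0, "tumor_read_fraction"),
    survival_time = round(pmin(t_event, t_censor), 2),
    event = as.integer(t_event <= t_censor),
    stringsAsFactors = FALSE
  )
  for (feat in names(cfg$features)) {
    p <- ifelse(group == "case", cfg$features[[feat]][1], cfg$features[[feat]][2])
    metadata[[feat]] <- as.integer(stats::runif(length(ids)) < p)
  }

  out <- list(repertoires = reps, metadata = metadata, truth = truth)
  if (!is.null(dir) && !clone_tables)
    tmerep_error("cannot write a cohort without clone tables", "tmerep_argument_error")
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      tmerep_error(paste("cannot create directory", dir), "tmerep_io_error")
    paths <- vapply(ids, function(id) {
      p <- file.path(dir, sprintf("%s_%s.airr.tsv", id, cfg$locus))
      write_airr(reps[[id]], p)
      p
    }, "")
    meta_path <- file.path(dir, "metadata.tsv")
    utils::write.table(metadata, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- list(clone_tables = paths, metadata = meta_path,
                      ground_truth = truth_path)
  }
  invisible(out)
}

#' Calibrate the group effect for a target clonality difference
#'
#' Finds the additive `sigma_shift` such that the generator's expected
#' clonality in the shifted group exceeds the baseline by `delta`. Expected
#' clonality is evaluated by Monte Carlo over `n_rep` draws of clone weights
#' at the configured clone-count range, with common random numbers fixed by
#' the config seed, so the result is deterministic and the objective smooth.
#'
#' @param cfg a [sim_config()] (its `sigma` is the baseline).
#' @param delta target increase in mean clonality (e.g. 0.10).
#' @param n_rep Monte Carlo replicates (default 40).
#' @return the calibrated shift (positive scalar).
#' @export
calibrate_sigma_shift <- function(cfg, delta, n_rep = 40L) {
  stopifnot(inherits(cfg, "sim_config"), delta > 0)
  set.seed(sample_seed(cfg, 0L, stream = 4L))
  ns <- if (length(cfg$clones_per_sample) == 2L)
    sample(cfg$clones_per_sample[1]:cfg$clones_per_sample[2], n_rep, replace = TRUE)
  else rep(cfg$clones_per_sample[1], n_rep)
  zs <- lapply(ns, stats::rnorm)
  mean_clonality <- function(sigma) {
    mean(vapply(zs, function(z) {
      w <- exp(sigma * z)
      f <- w / sum(w)
      1 + sum(f * log(f)) / log(length(f))
    }, numeric(1)))
  }
  base <- mean_clonality(cfg$sigma)
  stats::uniroot(function(s) mean_clonality(cfg$sigma + s) - base - delta,
                 interval = c(1e-3, 4), tol = 1e-4)$root
}
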