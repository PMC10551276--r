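#' Simulation configuration for a matched normal/tumor/EV cohort
#'
#' Defaults reproduce the structure of a deep-coverage mitochondrial
#' amplicon study of 32 metastatic TNBC patients: 7 of African and 25
#' of European ancestry, per-ancestry mean somatic loads of 7.5 and
#' 4.6 mutations per patient with a hard minimum of 3, mean read depth
#' 5000x, an 18% homoplasmic component in the heteroplasmy mixture,
#' a 4:1 transition:transversion draw, EV samples for 9/32 patients in
#' which each tumor mutation is detectable with probability 0.38 plus
#' about 1.2 EV-exclusive mutations per EV patient, and the bundled
#' hotspot panel injected at its per-mutation target frequencies.
#'
#' @param n_patients cohort size.
#' @param ancestry_split named fractions summing to 1 (converted to
#'   deterministic counts by largest remainder).
#' @param group_load_targets named mean somatic mutation counts per
#'   ancestry; each patient draws `somatic_min + Poisson(target -
#'   somatic_min)` mutations.
#' @param somatic_min minimum somatic mutations per patient.
#' @param germline_shared_per_ancestry haplogroup-background variants
#'   shared by all patients of an ancestry.
#' @param germline_private_mean Poisson mean of private germline
#'   variants per patient.
#' @param depth_mean,depth_size negative-binomial read-depth model
#'   (mean and dispersion size) per observation.
#' @param homoplasmic_weight probability a somatic mutation is
#'   homoplasmic.
#' @param hom_fraction_range,het_fraction_range uniform ranges for the
#'   true alt fraction of homoplasmic / heteroplasmic mutations.
#' @param ts_tv_odds transition:transversion odds for simulated
#'   substitutions.
#' @param ev_patient_fraction fraction of patients with an EV sample
#'   (deterministic count, first patients in id order).
#' @param ev_detection_prob per-mutation probability that an EV
#'   carries a tumor somatic mutation.
#' @param ev_exclusive_mean Poisson mean of EV-exclusive mutations per
#'   EV patient.
#' @param hotspot_injection data.frame `position`, `ref_base`,
#'   `alt_base`, `frequency` of recurrent somatic mutations injected
#'   per patient with the given Bernoulli frequency; `NULL` disables.
#' @param seed integer fixing all randomness.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 32L,
                              ancestry_split = c(African = 7 / 32,
                                                 European = 25 / 32),
                              group_load_targets = c(African = 7.5,
                                                     European = 4.6),
                              somatic_min = 3L,
                              germline_shared_per_ancestry = 20L,
                              germline_private_mean = 10,
                              depth_mean = 5000,
                              depth_size = 10,
                              homoplasmic_weight = 0.18,
                              hom_fraction_range = c(0.98, 1.0),
                              het_fraction_range = c(0.10, 0.90),
                              ts_tv_odds = 4,
                              ev_patient_fraction = 9 / 32,
                              ev_detection_prob = 0.38,
                              ev_exclusive_mean = 1.2,
                              hotspot_injection = default_hotspot_panel(),
                              seed = 1L) {
  stopifnot(n_patients >= 1,
            abs(sum(ancestry_split) - 1) < 1e-8,
            all(names(group_load_targets) %in% names(ancestry_split)),
            all(group_load_targets >= somatic_min),
            homoplasmic_weight >= 0, homoplasmic_weight <= 1,
            ev_detection_prob >= 0, ev_detection_prob <= 1,
            ev_patient_fraction >= 0, ev_patient_fraction <= 1,
            ts_tv_odds > 0, depth_mean > 0)
  if (!is.null(hotspot_injection)) {
    if (any(hotspot_injection$frequency > 1) ||
        any(hotspot_injection$frequency < 0)) {
      stop("hotspot target frequencies must be in [0, 1]", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "simulation_config")
}

## draw an alt base given a ref base with transition:transversion odds
draw_alt <- function(ref, odds) {
  transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(ref, function(r) {
    if (stats::runif(1) < odds / (odds + 1)) {
      transition_partner[[r]]
    } else {
      sample(setdiff(setdiff(c("A", "C", "G", "T"), r),
                     transition_partner[[r]]), 1L)
    }
  }, "", USE.NAMES = FALSE)
}

#' Simulate a matched normal/tumor/EV cohort with a truth ledger
#'
#' Generates per-patient variant observations with the structure the
#' somatic pipeline assumes: a shared-ancestry haplogroup background
#' plus private germline variants present in the normal, tumor and
#' (carry-over) EV profiles; somatic mutations present only in the
#' tumor, with read counts drawn depth ~ NegBin(mean, size) and
#' alt reads ~ Binomial(depth, alt fraction); EV profiles carrying each
#' tumor mutation with probability `ev_detection_prob` plus
#' EV-exclusive mutations. All germline keys are emitted as haplogroup
#' markers in the known-variant table. Identical seeds give identical
#' cohorts.
#'
#' @param config a [simulation_config()].
#' @param reference genome sequence (character scalar); defaults to
#'   the synthetic stand-in pinned to the hotspot panel's ref bases.
#' @return list with `patients` (records as in
#'   [build_patient_records()]), `ledger` (per-patient truth:
#'   `germline`, `somatic` with true alt fractions, `ev_carried`,
#'   `ev_exclusive`), `known_variants`, `manifest` (data.frame) and
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            reference = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)

  if (is.null(reference)) {
    cons <- config$hotspot_injection
    reference <- synthetic_reference(
      seed = config$seed + 7L,
      constraints = if (!is.null(cons))
        data.frame(position = cons$position, ref_base = cons$ref_base))
  }
  ref_at <- function(p) {
    if (length(p) == 0L) return(character(0))
    substring(reference, p, p)
  }

  n <- config$n_patients
  ## largest-remainder apportionment of ancestry counts
  raw <- config$ancestry_split * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  ancestry <- rep(names(counts), counts)
  pids <- sprintf("P%02d", seq_len(n))
  n_ev <- round(config$ev_patient_fraction * n)
  has_ev <- seq_len(n) <= n_ev

  ## ancestry-shared haplogroup backgrounds (disjoint positions)
  all_pos <- seq_len(MT_GENOME_LENGTH)
  shared <- list()
  used <- integer()
  for (g in names(counts)) {
    pos <- sample(setdiff(all_pos, used), config$germline_shared_per_ancestry)
    used <- c(used, pos)
    shared[[g]] <- data.frame(
      position = pos, ref_base = ref_at(pos),
      alt_base = draw_alt(ref_at(pos), config$ts_tv_odds),
      stringsAsFactors = FALSE)
  }
  hot <- config$hotspot_injection
  reserved <- c(used, if (!is.null(hot)) hot$position)

  draw_depth <- function(k) {
    stats::rnbinom(k, mu = config$depth_mean, size = config$depth_size) + 1L
  }
  obs_from_truth <- function(keys, af) {
    k <- nrow(keys)
    depth <- draw_depth(k)
    alt <- stats::rbinom(k, depth, af)
    data.frame(position = keys$position, ref_base = keys$ref_base,
               alt_base = keys$alt_base, total_depth = depth,
               ref_reads = depth - alt, alt_reads = alt,
               stringsAsFactors = FALSE)
  }
  draw_af <- function(k) {
    hom <- stats::runif(k) < config$homoplasmic_weight
    ifelse(hom,
           stats::runif(k, config$hom_fraction_range[1],
                        config$hom_fraction_range[2]),
           stats::runif(k, config$het_fraction_range[1],
                        config$het_fraction_range[2]))
  }
  new_keys <- function(k, exclude) {
    pos <- sample(setdiff(all_pos, exclude), k)
    data.frame(position = pos, ref_base = ref_at(pos),
               alt_base = draw_alt(ref_at(pos), config$ts_tv_odds),
               stringsAsFactors = FALSE)
  }

  patients <- list()
  ledger <- list(patients = list(),
                 hotspot_targets = hot,
                 group_load_targets = config$group_load_targets,
                 homoplasmic_weight = config$homoplasmic_weight,
                 ev_detection_prob = config$ev_detection_prob)
  manifest <- list()

  ## draw every patient's germline first so somatic positions can be
  ## kept disjoint from the cohort-wide germline pool (all germline
  ## keys become haplogroup markers; a somatic draw landing on another
  ## patient's germline site would otherwise be excluded by design)
  germline <- list()
  germ_pool <- reserved
  for (i in seq_len(n)) {
    n_priv <- stats::rpois(1L, config$germline_private_mean)
    priv <- new_keys(n_priv, germ_pool)
    germ_pool <- c(germ_pool, priv$position)
    germline[[pids[i]]] <- rbind(shared[[ancestry[i]]], priv)
  }

  for (i in seq_len(n)) {
    pid <- pids[i]
    anc <- ancestry[i]
    germ <- germline[[pid]]
    ## somatic: injected hotspots + private draws up to the target count
    hot_rows <- if (!is.null(hot)) {
      hot[stats::runif(nrow(hot)) < hot$frequency,
          c("position", "ref_base", "alt_base"), drop = FALSE]
    } else hot
    target <- config$group_load_targets[[anc]]
    n_som <- config$somatic_min +
      stats::rpois(1L, max(0, target - config$somatic_min))
    n_extra <- max(0L, n_som - NROW(hot_rows))
    som <- rbind(hot_rows, new_keys(n_extra, germ_pool))
    som_af <- draw_af(nrow(som))

    normal_obs <- obs_from_truth(germ, af = 1)
    tumor_obs <- rbind(obs_from_truth(germ, af = 1),
                       obs_from_truth(som, som_af))

    samples <- list(
      normal = new_sample_profile(paste0(pid, "-N"), "normal",
                                  mean_coverage = config$depth_mean,
                                  observations = normal_obs),
      tumor = new_sample_profile(paste0(pid, "-T"), "tumor",
                                 mean_coverage = config$depth_mean,
                                 observations = tumor_obs)
    )
    led <- list(
      germline = mutation_key(germ$position, germ$ref_base, germ$alt_base),
      somatic = data.frame(
        key = mutation_key(som$position, som$ref_base, som$alt_base),
        position = som$position, ref_base = som$ref_base,
        alt_base = som$alt_base, true_alt_fraction = som_af,
        stringsAsFactors = FALSE),
      ev_carried = character(),
      ev_exclusive = character())

    if (has_ev[i]) {
      carried <- stats::runif(nrow(som)) < config$ev_detection_prob
      n_excl <- stats::rpois(1L, config$ev_exclusive_mean)
      excl <- new_keys(n_excl, c(germ_pool, som$position))
      excl_af <- draw_af(n_excl)
      ev_obs <- rbind(obs_from_truth(germ, af = 1),
                      obs_from_truth(som[carried, , drop = FALSE],
                                     som_af[carried]),
                      obs_from_truth(excl, excl_af))
      samples$EV <- new_sample_profile(paste0(pid, "-EV"), "EV",
                                       mean_coverage = config$depth_mean,
                                       observations = ev_obs)
      led$ev_carried <- led$somatic$key[carried]
      led$ev_exclusive <- mutation_key(excl$position, excl$ref_base,
                                       excl$alt_base)
    }

    patients[[pid]] <- list(patient_id = pid, ancestry = anc,
                            stage = sample(c("I", "II", "III", "IV"), 1L),
                            age = round(stats::rnorm(1L, 58, 12)),
                            samples = samples)
    ledger$patients[[pid]] <- led
    for (tis in names(samples)) {
      manifest[[length(manifest) + 1L]] <- data.frame(
        patient_id = pid, sample_id = samples[[tis]]$sample_id,
        tissue = tis, ancestry = anc,
        stage = patients[[pid]]$stage, age = patients[[pid]]$age,
        stringsAsFactors = FALSE)
    }
  }

  germ_all <- unique(do.call(rbind, c(
    lapply(patients, function(p)
      p$samples$normal$observations[c("position", "ref_base", "alt_base")]))))
  known <- data.frame(
    position = germ_all$position, ref_base = germ_all$ref_base,
    alt_base = germ_all$alt_base,
    reported_in_databases = TRUE, pathogenic = FALSE,
    haplogroup_marker = TRUE, stringsAsFactors = FALSE)
  known <- known[order(known$position, known$ref_base, known$alt_base), ]
  rownames(known) <- NULL

  list(patients = patients, ledger = ledger, known_variants = known,
       manifest = do.call(rbind, manifest), reference = reference,
       config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCFv4.2 file per sample (plain text, GATK-style
#' `GT:AD:DP` fields on contig `chrM`), a manifest TSV, the
#' known-variant (haplogroup marker) TSV, the reference FASTA and the
#' truth ledger as JSON. Output is byte-deterministic for a given
#' cohort.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return (invisibly) named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (p in cohort$patients) {
    for (prof in p$samples) {
      path <- file.path(dir, paste0(prof$sample_id, ".vcf"))
      write_profile_vcf(prof, path)
      paths[prof$sample_id] <- path
    }
  }
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(cohort$manifest, man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kv <- file.path(dir, "known_variants.tsv")
  df <- cohort$known_variants
  for (col in c("reported_in_databases", "pathogenic", "haplogroup_marker")) {
    df[[col]] <- ifelse(df[[col]], "yes", "no")
  }
  utils::write.table(df, kv, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "synthetic_reference.fasta")
  writeLines(c(">synthetic_rCRS_standin length=16569",
               substring(cohort$reference,
                         seq(1, nchar(cohort$reference), 70),
                         pmin(seq(70, nchar(cohort$reference) + 69, 70),
                              nchar(cohort$reference)))), fa)
  lj <- file.path(dir, "truth_ledger.json")
  jsonlite::write_json(cohort$ledger, lj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = man, known_variants = kv,
              reference = fa, ledger = lj))
}

## minimal deterministic VCFv4.2 writer for one sample profile
write_profile_vcf <- function(profile, path) {
  obs <- profile$observations
  obs <- obs[order(obs$position, obs$alt_base), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           profile$sample_id))
  body <- if (nrow(obs)) {
    sprintf("chrM\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
            obs$position, obs$ref_base, obs$alt_base,
            obs$ref_reads, obs$alt_reads, obs$total_depth)
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Compare pipeline output against the simulation truth ledger
#'
#' Re-measures, on a simulated cohort, how well the somatic caller and
#' the downstream aggregates recover the generator's parameters:
#' sensitivity and precision of somatic calls against the ledger,
#' pooled tumor-to-EV traceability vs the configured detection
#' probability, occurrence-level homoplasmic share vs the configured
#' mixture weight, transition share vs the configured odds, and
#' per-ancestry mutational loads vs their targets.
#'
#' @param cohort result of [simulate_cohort()].
#' @param config a [filter_config()] used for the pipeline run.
#' @return list of class `recovery_report`; see fields in source.
#' @export
evaluate_recovery <- function(cohort, config = filter_config()) {
  res <- call_cohort(cohort$patients,
                     known = cohort$known_variants, config = config)
  mut <- res$mutations
  called <- split(mutation_key(mut$position, mut$ref_base, mut$alt_base),
                  mut$patient_id)
  tp <- fp <- fn <- 0L
  for (pid in names(cohort$ledger$patients)) {
    truth <- cohort$ledger$patients[[pid]]$somatic$key
    got <- unique(called[[pid]])
    tp <- tp + length(intersect(got, truth))
    fp <- fp + length(setdiff(got, truth))
    fn <- fn + length(setdiff(truth, got))
  }
  sens <- if (tp + fn) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp) tp / (tp + fp) else NA_real_

  ## EV side: filtered EV observations per patient
  ev_rows <- list()
  for (p in cohort$patients) {
    if (is.null(p$samples$EV)) next
    prof <- apply_read_filters(p$samples$EV, config)
    if (nrow(prof$observations)) {
      ev_rows[[p$patient_id]] <- cbind(patient_id = p$patient_id,
                                       prof$observations)
    }
  }
  normal_rows <- do.call(rbind, lapply(cohort$patients, function(p) {
    cbind(patient_id = p$patient_id, p$samples$normal$observations)
  }))
  trace <- if (length(ev_rows)) {
    traceability(mut, do.call(rbind, ev_rows), normal_rows)
  } else NULL

  cfg <- cohort$config
  hom_share <- mean(mut$heteroplasmy == "homoplasmic") * 100
  ts_share <- mean(mut$substitution_class == "transition") * 100

  anc <- vapply(cohort$patients, `[[`, "", "ancestry")
  groups <- data.frame(patient_id = names(anc), group = unname(anc),
                       stringsAsFactors = FALSE)
  loads <- mutational_load(mut, groups)
  load_err <- loads$load -
    unname(cfg$group_load_targets[loads$group])

  structure(list(
    somatic_sensitivity = sens,
    somatic_precision = prec,
    traceability_pct = if (!is.null(trace)) trace$traceability_pct else NA,
    traceability_error = if (!is.null(trace))
      trace$traceability_pct - cfg$ev_detection_prob * 100 else NA,
    homoplasmic_share_pct = hom_share,
    homoplasmic_share_error = hom_share - cfg$homoplasmic_weight * 100,
    transition_share_pct = ts_share,
    transition_share_error = ts_share -
      cfg$ts_tv_odds / (cfg$ts_tv_odds + 1) * 100,
    group_loads = loads,
    group_load_errors = stats::setNames(load_err, loads$group),
    n_calls = nrow(mut)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> sensitivity %.3f, precision %.3f, %d calls\n",
              x$somatic_sensitivity, x$somatic_precision, x$n_calls))
  cat(sprintf("  traceability %.1f%% (err %+.1f), homoplasmic %.1f%% (err %+.1f), transitions %.1f%% (err %+.1f)\n",
              x$traceability_pct, x$traceability_error,
              x$homoplasmic_share_pct, x$homoplasmic_share_error,
              x$transition_share_pct, x$transition_share_error))
  invisible(x)
}
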