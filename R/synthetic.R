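#' Configuration for the synthetic study generator
#'
#' Describes a simulated screening study with the same shape as the real
#' one: random protein sequences, activities that are a smooth (linear)
#' function of the true PseAAC features plus Gaussian measurement noise, and
#' halo diameters that increase monotonically with a latent activity score.
#'
#' Defaults mirror the real study's conditions: 41 strains, GH11-xylanase
#' lengths (180–230 residues), three assay conditions, activities centred
#' near 400 IU/ml with spread 200 IU/ml (the range of the assayed strains),
#' and measurement noise `sigma = 50` IU/ml. Residues are sampled uniformly
#' over the 20-letter alphabet by default; pass a named `composition` vector
#' for biased sampling.
#'
#' @param n_sequences Number of simulated strains (default 41).
#' @param length_range Integer range of sequence lengths (default 180–230).
#' @param seed Master seed; every downstream draw derives from it.
#' @param params [pseaac_params()] defining the true feature map.
#' @param sigma Activity noise SD in IU/ml (default 50; 0 gives a noiseless
#'   linear target).
#' @param activity_mean,activity_sd Centre and spread (IU/ml) to which the
#'   latent linear score is rescaled, per condition.
#' @param beta Optional `(20+2*lambda) x n_conditions` coefficient matrix;
#'   drawn standard-normal from `seed` when `NULL`.
#' @param halo_range Halo diameters (mm) that the lowest/highest latent
#'   scores map to (default 2–8 mm, the observed range).
#' @param halo_noise_sd SD (mm) of halo measurement noise (default 0.3).
#' @param composition Optional named residue-probability vector for biased
#'   sequence sampling.
#' @return A `xyl_sim_config` object.
#' @export
sim_config <- function(n_sequences = 41L, length_range = c(180L, 230L), seed = 1L,
                       params = pseaac_params(), sigma = 50,
                       activity_mean = 400, activity_sd = 200, beta = NULL,
                       halo_range = c(2, 8), halo_noise_sd = 0.3,
                       composition = NULL) {
  if (min(length_range) <= params$lambda) {
    abort("sequence lengths must exceed lambda", class = "xyl_param_error")
  }
  if (sigma < 0) abort("sigma must be >= 0", class = "xyl_param_error")
  structure(
    list(n_sequences = as.integer(n_sequences),
         length_range = as.integer(length_range), seed = as.integer(seed),
         params = params, sigma = sigma, activity_mean = activity_mean,
         activity_sd = activity_sd, beta = beta, halo_range = halo_range,
         halo_noise_sd = halo_noise_sd, composition = composition),
    class = "xyl_sim_config"
  )
}

#' Simulate protein sequences
#'
#' I.i.d. residues over the canonical alphabet (uniform, or biased by
#' `cfg$composition`) at lengths drawn uniformly from `cfg$length_range`.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with `id` (`SYN001`, ...) and `residues`.
#' @examples
#' simulate_sequences(sim_config(n_sequences = 3, seed = 7))
#' @export
simulate_sequences <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "xyl_sim_config"))
  n <- cfg$n_sequences
  if (n == 0) return(tibble(id = character(0), residues = character(0)))
  prob <- if (is.null(cfg$composition)) NULL else cfg$composition[AA_ALPHABET]
  withr::with_seed(cfg$seed, {
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n, replace = TRUE)
    res <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  tibble(id = sprintf("SYN%03d", seq_len(n)), residues = res)
}

# Coefficients for the linear activity surface, one column per condition.
sim_beta <- function(cfg, p, n_conditions = length(CONDITION_LABELS)) {
  if (!is.null(cfg$beta)) {
    beta <- as.matrix(cfg$beta)
    if (nrow(beta) != p) {
      abort(sprintf("beta has %d rows; features have %d columns", nrow(beta), p),
            class = "xyl_dimension_error")
    }
    return(beta)
  }
  withr::with_seed(cfg$seed + 1L, matrix(stats::rnorm(p * n_conditions), p, n_conditions))
}

#' Simulate enzyme activities from PseAAC features
#'
#' Activities are an affine rescaling of the linear score `X beta` (so the
#' cohort has mean `activity_mean` and SD `activity_sd` before noise) plus
#' Gaussian noise of SD `sigma`, independently per condition, then clipped at
#' 0 IU/ml (the unit's domain). The number of clipped values is reported in
#' the `clipped` attribute.
#'
#' @param features Feature tibble (`id` + `e1..eN`, from
#'   [extract_features()]).
#' @param cfg A [sim_config()].
#' @return A tibble `id`, `act_pH4_T60`, `act_pH4_T26`, `act_pH6_T26`, with
#'   attribute `clipped` (count of zero-clipped cells).
#' @export
simulate_activities <- function(features, cfg = sim_config()) {
  stopifnot(inherits(cfg, "xyl_sim_config"))
  X <- feature_matrix(features)
  n <- nrow(X)
  beta <- sim_beta(cfg, ncol(X))
  acts <- withr::with_seed(cfg$seed + 2L, {
    vapply(seq_len(ncol(beta)), function(j) {
      latent <- as.numeric(X %*% beta[, j])
      sdl <- stats::sd(latent)
      z <- if (n < 2 || sdl == 0) rep(0, n) else (latent - mean(latent)) / sdl
      cfg$activity_mean + cfg$activity_sd * z + stats::rnorm(n, 0, cfg$sigma)
    }, numeric(n))
  })
  clipped <- sum(acts < 0)
  acts[acts < 0] <- 0
  colnames(acts) <- paste0("act_", CONDITION_LABELS)
  out <- bind_cols(tibble(id = as.character(features$id)), as_tibble(acts))
  attr(out, "clipped") <- clipped
  out
}

#' Simulate halo diameters and classes
#'
#' The halo diameter is a monotone (affine) map of a latent activity score —
#' the mean of the per-condition activities — onto `cfg$halo_range` mm, plus
#' Gaussian noise, floored at 0.5 mm; classes come from [classify_halo()].
#'
#' @param activities Tibble from [simulate_activities()].
#' @param cfg A [sim_config()].
#' @param thresholds A [halo_thresholds()].
#' @return A tibble `id`, `halo_mm`, `real_class`.
#' @export
simulate_halos <- function(activities, cfg = sim_config(),
                           thresholds = halo_thresholds()) {
  stopifnot(inherits(cfg, "xyl_sim_config"))
  act_cols <- grep("^act_", names(activities), value = TRUE)
  score <- rowMeans(as.matrix(activities[act_cols]))
  n <- length(score)
  if (n == 0) {
    return(tibble(id = character(0), halo_mm = numeric(0),
                  real_class = factor(character(0), levels = c("L", "M", "H"),
                                      ordered = TRUE)))
  }
  rng <- range(score)
  unit <- if (n < 2 || diff(rng) == 0) rep(0.5, n) else (score - rng[1]) / diff(rng)
  halo <- cfg$halo_range[1] + unit * diff(cfg$halo_range)
  halo <- withr::with_seed(cfg$seed + 3L,
                           pmax(0.5, halo + stats::rnorm(n, 0, cfg$halo_noise_sd)))
  tibble(id = as.character(activities$id), halo_mm = halo,
         real_class = classify_halo(halo, thresholds))
}

#' Simulate a complete synthetic study
#'
#' Chains [simulate_sequences()], [extract_features()],
#' [simulate_activities()] and [simulate_halos()] into a dataset with exactly
#' the shape of the real one, optionally writing the FASTA and strain-table
#' files so the whole downstream pipeline runs format-identically on
#' synthetic data.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; writes `sequences.fasta` and
#'   `strains.csv`.
#' @return A list: `sequences`, `features`, `strains` (accession = id,
#'   strain = id, halo, class, activities), `clipped`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  seqs <- simulate_sequences(cfg)
  feats <- extract_features(seqs, cfg$params)
  acts <- simulate_activities(feats, cfg)
  halos <- simulate_halos(acts, cfg)
  strains <- bind_cols(
    tibble(accession = seqs$id, strain = seqs$id),
    select(halos, "halo_mm", "real_class"),
    select(acts, -"id")
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(seqs, file.path(dir, "sequences.fasta"))
    write_strain_table(strains, file.path(dir, "strains.csv"))
  }
  list(sequences = seqs, features = feats, strains = strains,
       clipped = attr(acts, "clipped"))
}
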