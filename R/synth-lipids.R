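#' Simulate a lipidomics abundance table with known affected lipids
#'
#' Internal-standard-corrected lipid abundances are drawn log-normally per
#' lipid (baselines spanning several decades), with a multiplicative group
#' effect on a chosen set of affected lipids and sporadic non-detects
#' encoded as exact zeros. The sample layout mirrors a developmental
#' time-course design: control samples at each of several timepoints and a
#' test group sampled at the first timepoint.
#'
#' @param n_lipids Number of lipids.
#' @param class_labels Character vector of lipid class names to sample from
#'   (recycled over lipids with realistic weights when left at default).
#' @param n_samples_per_group Control samples per timepoint.
#' @param n_test_samples Test-group samples (all at the first timepoint).
#' @param timepoints_h Numeric timepoint labels (hours) for the control
#'   group.
#' @param missing_prob Per-cell probability of a sporadic non-detect, in
#'   \[0, 1), on top of the detection-limit censoring.
#' @param lod_quantile Detection limit, expressed as a quantile of the
#'   baseline abundance distribution: abundances below it are censored to
#'   zero. The default (0.3) leaves roughly the fraction of lipids passing
#'   the half-plus-one filter seen in real worm lipidomes (~two thirds).
#' @param effect_multipliers Either `NULL` (a default set of 9 affected
#'   lysophospholipids with multiplier 2.5, the shape of a signalling-lipid
#'   effect) or a named numeric vector `lipid_id -> multiplier` applied to
#'   the test group; unaffected lipids keep multiplier exactly 1.
#' @param sdlog Within-group log-normal noise (sdlog scale).
#' @param seed Integer seed.
#'
#' @return A list with `table` (tibble: `lipid_id`, `class`, one column per
#'   sample), `samples` (tibble: `sample_id`, `group`, `timepoint_h`), and
#'   `truth` (list: `affected_lipids`, `effect_multipliers`,
#'   `missing_cells`).
#' @export
gen_lipid_table <- function(n_lipids = 397,
                            class_labels = NULL,
                            n_samples_per_group = 5,
                            n_test_samples = 10,
                            timepoints_h = c(50, 53, 56),
                            missing_prob = 0.01,
                            lod_quantile = 0.3,
                            effect_multipliers = NULL,
                            sdlog = 0.25,
                            seed = 1L) {
  if (missing_prob < 0 || missing_prob >= 1) {
    abort("`missing_prob` must be in [0, 1).")
  }
  with_seed(seed, {
    if (is.null(class_labels)) {
      class_labels <- sample(
        c("TG", "PC", "PE", "LPC", "LPE", "SM", "PI", "PS", "Cer", "DG"),
        n_lipids, replace = TRUE,
        prob = c(0.30, 0.17, 0.12, 0.06, 0.05, 0.08, 0.06, 0.05, 0.06, 0.05)
      )
    } else {
      class_labels <- rep_len(class_labels, n_lipids)
    }
    lipid_ids <- sprintf("%s_%03d", class_labels, seq_len(n_lipids))

    baseline <- rlnorm(n_lipids, meanlog = -1, sdlog = 1.5)
    lod <- if (lod_quantile > 0) {
      stats::quantile(baseline, lod_quantile, names = FALSE)
    } else {
      0
    }

    if (is.null(effect_multipliers)) {
      # default: 9 affected lysophospholipids, comfortably above the
      # detection limit (effects are only observable on detected lipids)
      lyso <- which(class_labels %in% c("LPC", "LPE") & baseline > 3 * lod)
      n_eff <- min(9L, length(lyso))
      eff_ids <- lipid_ids[sort(sample(lyso, n_eff))]
      effect_multipliers <- setNames(rep(2.5, n_eff), eff_ids)
    }
    mult <- setNames(rep(1, n_lipids), lipid_ids)
    unknown <- setdiff(names(effect_multipliers), lipid_ids)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown lipid id in `effect_multipliers`: %s",
                    unknown[1]))
    }
    mult[names(effect_multipliers)] <- effect_multipliers

    ctrl <- tidyr::expand_grid(timepoint_h = timepoints_h,
                               rep = seq_len(n_samples_per_group))
    samples <- dplyr::bind_rows(
      tibble::tibble(
        sample_id = sprintf("wt_%gh_%d", ctrl$timepoint_h, ctrl$rep),
        group = "control", timepoint_h = ctrl$timepoint_h
      ),
      tibble::tibble(
        sample_id = sprintf("mut_%gh_%d", timepoints_h[1],
                            seq_len(n_test_samples)),
        group = "test", timepoint_h = timepoints_h[1]
      )
    )
    n_samples <- nrow(samples)

    abund <- matrix(0, n_lipids, n_samples,
                    dimnames = list(lipid_ids, samples$sample_id))
    for (j in seq_len(n_samples)) {
      m <- if (samples$group[j] == "test") baseline * mult else baseline
      abund[, j] <- rlnorm(n_lipids, meanlog = log(m), sdlog = sdlog)
    }

    # non-detects: instrument detection limit censoring plus sporadic
    # dropout; low-abundance lipids are censored in many or all samples
    drop <- abund < lod |
      matrix(runif(n_lipids * n_samples) < missing_prob,
             n_lipids, n_samples)
    abund[drop] <- 0
    missing_cells <- tibble::tibble(
      lipid_id = lipid_ids[row(drop)[drop]],
      sample_id = samples$sample_id[col(drop)[drop]]
    )

    table <- dplyr::bind_cols(
      tibble::tibble(lipid_id = lipid_ids, class = class_labels),
      tibble::as_tibble(abund)
    )
    list(
      table = table,
      samples = samples,
      truth = list(
        affected_lipids = names(effect_multipliers),
        effect_multipliers = mult,
        missing_cells = missing_cells
      )
    )
  })
}
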