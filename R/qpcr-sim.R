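# Synthetic qPCR threshold-cycle tables. The generator states expression as
# true 2^-deltaCT levels per gene x stage; CT values follow from
# CT_target = CT_ref - log2(level) + noise, so the comparative-CT pipeline
# inverts the generator exactly when noise is zero.

#' Define a qPCR expression scenario
#'
#' @param levels Named list: one named numeric vector of true `2^-deltaCT`
#'   values per target gene, with one entry per stage (all > 0). The stage
#'   names must agree across genes.
#' @param reference Reference (housekeeping) gene label.
#' @param base_ct_ref Mean threshold cycle of the reference gene.
#' @param ref_ct_sd SD of the reference-gene CT draw, cycles (plate-to-plate
#'   variation; cancels in deltaCT).
#' @param ct_noise_sd SD of the target-gene CT measurement noise, cycles.
#' @param replicates Biological replicates per stage (>= 1).
#' @param rounds Technical qPCR rounds per replicate (>= 1).
#' @return An object of class `ct_scenario`.
#' @export
ct_scenario <- function(levels, reference = "rna28s", base_ct_ref = 16,
                        ref_ct_sd = 0.15, ct_noise_sd = 0.1,
                        replicates = 3, rounds = 2) {
  stopifnot(is.list(levels), length(levels) >= 1, replicates >= 1,
            rounds >= 1, ct_noise_sd >= 0, ref_ct_sd >= 0)
  stages <- names(levels[[1]])
  if (is.null(stages)) stop("expression levels must be named by stage",
                            call. = FALSE)
  for (g in names(levels)) {
    if (!identical(names(levels[[g]]), stages)) {
      stop("all genes must list the same stages in the same order",
           call. = FALSE)
    }
    if (any(levels[[g]] <= 0)) stop("2^-deltaCT levels must be > 0",
                                    call. = FALSE)
  }
  structure(list(levels = levels, stages = stages, reference = reference,
                 base_ct_ref = base_ct_ref, ref_ct_sd = ref_ct_sd,
                 ct_noise_sd = ct_noise_sd, replicates = as.integer(replicates),
                 rounds = as.integer(rounds)),
            class = "ct_scenario")
}

#' Developmental-expression scenario for the zebrafish PepT1 paralogues
#'
#' Encodes the published 1-7 dpf (days post-fertilisation) expression
#' course: *pept1a* fold-changes vs 1 dpf of (1, ~1, 0.61, 2.00, 2.66,
#' 6.73, 1.81) — the 3 dpf point below control is stored as the ratio
#' 0.61 — and *pept1b* rising from a very faint 1 dpf signal through
#' ~1.5e3-fold (2 dpf) and ~8.8e3-fold (4 dpf) to ~5.3e5-fold (7 dpf),
#' with unpublished stages log-interpolated. Base `2^-deltaCT` levels
#' (0.02 for *pept1a*, 2e-6 for *pept1b* at 1 dpf) set the absolute scale,
#' which fold-changes and the paralogue ratio are invariant to; with these
#' levels the *pept1a*/*pept1b* ratio is > 1 from 1 to 4 dpf and < 1 from
#' 5 to 7 dpf.
#'
#' @inheritParams ct_scenario
#' @return A [ct_scenario()] with genes `pept1a` and `pept1b`.
#' @export
ct_scenario_fig7 <- function(ct_noise_sd = 0.1, replicates = 3, rounds = 2) {
  stages <- paste0(1:7, "dpf")
  fold_a <- c(1, 1, 0.61, 2.00, 2.66, 6.73, 1.81)
  anchors_b <- c(`1` = 1, `2` = 1.5e3, `4` = 8.8e3, `7` = 5.3e5)
  logf <- stats::approx(x = as.numeric(names(anchors_b)), y = log10(anchors_b),
                        xout = 1:7)$y
  fold_b <- 10^logf
  levels <- list(pept1a = stats::setNames(0.02 * fold_a, stages),
                 pept1b = stats::setNames(2e-6 * fold_b, stages))
  ct_scenario(levels, reference = "rna28s", ct_noise_sd = ct_noise_sd,
              replicates = replicates, rounds = rounds)
}

#' Generate a synthetic threshold-cycle table
#'
#' For every (stage, replicate, round) a reference-gene CT is drawn around
#' `base_ct_ref`; each target gene's CT is then
#' `CT_ref - log2(level) + N(0, ct_noise_sd)`. With `ct_noise_sd = 0` the
#' comparative-CT pipeline recovers the scenario's levels exactly; halving
#' a true level raises the mean target CT by one cycle.
#'
#' @param scenario A [ct_scenario()].
#' @param seed Integer seed (or `NULL`).
#' @return A `ct_table` data frame with columns `gene`, `stage`,
#'   `replicate`, `round`, `ct` (reference-gene rows included).
#' @export
generate_ct_table <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "ct_scenario"))
  grid <- expand.grid(round = seq_len(scenario$rounds),
                      replicate = seq_len(scenario$replicates),
                      stage = scenario$stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  .run_seeded(seed, {
    ct_ref <- scenario$base_ct_ref +
      stats::rnorm(nrow(grid), 0, scenario$ref_ct_sd)
    out <- data.frame(gene = scenario$reference, stage = grid$stage,
                      replicate = grid$replicate, round = grid$round,
                      ct = ct_ref)
    for (g in names(scenario$levels)) {
      lv <- scenario$levels[[g]][grid$stage]
      ct_g <- ct_ref - log2(lv) +
        stats::rnorm(nrow(grid), 0, scenario$ct_noise_sd)
      out <- rbind(out, data.frame(gene = g, stage = grid$stage,
                                   replicate = grid$replicate,
                                   round = grid$round, ct = unname(ct_g)))
    }
    rownames(out) <- NULL
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
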