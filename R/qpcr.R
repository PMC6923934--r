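# Comparative-CT qPCR analytics: primer efficiency from dilution series,
# 2^-deltaCT expression, fold-change vs a control stage, paralogue ratios.

#' Primer efficiency from a dilution series
#'
#' Ordinary least-squares line of threshold cycle vs log10(dilution)
#' (standard-curve method). The slope `m` satisfies `m = -(1/log10 E)`, so
#' the amplification efficiency is recovered as `E = 10^(-1/m)` (E = 2 for
#' perfect doubling, i.e. a slope of -3.3219 cycles per tenfold dilution).
#'
#' @param dilution Relative template amounts (e.g. 1, 0.1, 0.01 for a
#'   tenfold series); at least three distinct positive values.
#' @param ct Threshold cycles, one per dilution.
#' @return An object of class `primer_efficiency`: `slope` (cycles per
#'   log10 dilution), `intercept`, `efficiency`, `r_squared`, `n`.
#' @export
primer_efficiency <- function(dilution, ct) {
  stopifnot(length(dilution) == length(ct))
  if (length(dilution) < 3) stop("need at least 3 dilutions", call. = FALSE)
  if (any(dilution <= 0)) stop("dilutions must be > 0", call. = FALSE)
  if (length(unique(dilution)) < 2) {
    stop("dilution values are degenerate", call. = FALSE)
  }
  x <- log10(dilution)
  fit <- stats::lm(ct ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m == 0) stop("degenerate dilution series",
                                    call. = FALSE)
  # R^2 computed directly (summary.lm warns on zero-residual series)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  structure(list(slope = m, intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / m), r_squared = r2,
                 n = length(ct)),
            class = "primer_efficiency")
}

#' @export
print.primer_efficiency <- function(x, ...) {
  cat(sprintf(
    "Primer efficiency: slope %.4g cycles/log10-dilution -> E = %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$efficiency, x$r_squared, x$n))
  invisible(x)
}

.check_ct_table <- function(table) {
  need <- c("gene", "stage", "replicate", "round", "ct")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("CT table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("CT values must be positive and finite", call. = FALSE)
  }
  invisible(table)
}

#' Relative expression by the comparative-CT (2^-deltaCT) method
#'
#' For every (stage, replicate, round), `deltaCT = CT_target - CT_ref` and
#' the relative level is `2^-deltaCT`. Aggregation order is a fixed
#' contract matching standard practice: mean over technical rounds within
#' each biological replicate first, then mean and SD across replicates.
#' Averaging is done on the `2^-deltaCT` scale (arithmetic mean);
#' `geometric = TRUE` switches to the geometric mean (equivalent to
#' averaging deltaCT first) for users who prefer the log-scale convention.
#'
#' @param table A CT table (columns `gene`, `stage`, `replicate`, `round`,
#'   `ct`), e.g. from [generate_ct_table()] or [read_ct_table()].
#' @param target Target gene label.
#' @param reference Reference (housekeeping) gene label; must be present
#'   in every (stage, replicate, round) where the target is.
#' @param geometric Use geometric instead of arithmetic means.
#' @return An object of class `expression_result`: `replicate_values`
#'   (per-replicate means), `summary` (per-stage `mean`, `sd`, `n`),
#'   `target`, `reference`, `stages`.
#' @export
expression_2dct <- function(table, target, reference, geometric = FALSE) {
  .check_ct_table(table)
  tgt <- table[table$gene == target, ]
  ref <- table[table$gene == reference, ]
  if (!nrow(tgt)) stop("target gene '", target, "' not in table",
                       call. = FALSE)
  key <- function(d) paste(d$stage, d$replicate, d$round, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  miss <- !(key(tgt) %in% names(ref_ct))
  if (any(miss)) {
    stop("reference gene '", reference,
         "' missing for some (stage, replicate, round) of the target",
         call. = FALSE)
  }
  dct <- tgt$ct - ref_ct[key(tgt)]
  val <- 2^(-dct)
  agg <- function(x) if (geometric) exp(mean(log(x))) else mean(x)
  per_rep <- stats::aggregate(
    list(value = val),
    by = list(stage = tgt$stage, replicate = tgt$replicate), FUN = agg)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$stage), function(g) {
    data.frame(stage = g$stage[1], mean = agg(g$value),
               sd = stats::sd(g$value), n = nrow(g))
  }))
  stages <- unique(tgt$stage)  # preserve table order
  summ <- summ[match(stages, summ$stage), ]
  rownames(summ) <- NULL
  structure(list(replicate_values = per_rep, summary = summ,
                 target = target, reference = reference, stages = stages,
                 geometric = geometric),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("2^-deltaCT expression of %s (reference %s):\n", x$target,
              x$reference))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fold-change of expression versus a control stage
#'
#' Divides each stage's mean `2^-deltaCT` by the control stage's mean, so
#' the control maps to exactly 1. Stages expressed below the control give
#' ratios in (0, 1) — some reports render e.g. 0.61 as a "negative
#' fold-change (-0.61)"; see [format_fold_change()] for that display
#' convention. Stored values are always ratios.
#'
#' @param expr An [expression_2dct()] result.
#' @param control_stage Stage label used as the fold-change reference.
#' @return `expr` with `fold` columns added to `summary` and
#'   `replicate_values`, and `control_stage` recorded.
#' @export
fold_change <- function(expr, control_stage) {
  stopifnot(inherits(expr, "expression_result"))
  idx <- match(control_stage, expr$summary$stage)
  if (is.na(idx)) stop("control stage '", control_stage, "' not present",
                       call. = FALSE)
  ctrl <- expr$summary$mean[idx]
  expr$summary$fold <- expr$summary$mean / ctrl
  expr$replicate_values$fold <- expr$replicate_values$value / ctrl
  expr$control_stage <- control_stage
  expr
}

#' Display convention for sub-control fold-changes
#'
#' Renders a fold-change ratio the way some developmental-expression
#' reports print it: values >= 1 as "+x.xx", values < 1 as "-x.xx" where
#' the magnitude is the (positive) ratio itself. Display only; never used
#' in stored values.
#'
#' @param fold Fold-change ratios (> 0).
#' @param digits Decimal places.
#' @return Character vector.
#' @export
format_fold_change <- function(fold, digits = 2) {
  ifelse(fold >= 1, sprintf("+%.*f", digits, fold),
         sprintf("-%.*f", digits, fold))
}

#' Per-stage expression ratio between two genes
#'
#' Ratio of mean `2^-deltaCT` levels (gene a over gene b) at each stage,
#' with an indicator for ratios above 1 — used to locate the stage at
#' which one paralogue overtakes the other.
#'
#' @param expr_a,expr_b [expression_2dct()] results over identical stages.
#' @return Data frame `stage`, `ratio`, `above_one`.
#' @export
gene_ratio <- function(expr_a, expr_b) {
  stopifnot(inherits(expr_a, "expression_result"),
            inherits(expr_b, "expression_result"))
  if (!identical(expr_a$stages, expr_b$stages)) {
    stop("the two expression results cover different stages", call. = FALSE)
  }
  ratio <- expr_a$summary$mean / expr_b$summary$mean
  data.frame(stage = expr_a$summary$stage, ratio = ratio,
             above_one = ratio > 1)
}
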