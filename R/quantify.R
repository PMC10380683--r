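# Digital-PCR estimators: Poisson concentration with delta-method
# confidence intervals, vector copy number by Titin normalization, HR
# efficiency relative to the limiting vector, concatemer fraction after
# AleI digestion, expression specificity, and the assembled report.

#' Poisson concentration estimate from droplet counts
#'
#' With `k` positive droplets out of `N`, the mean occupancy is
#' `lambda_hat = -ln(1 - k/N)` copies/droplet; the 95% CI uses the delta
#' method, `lambda_hat +/- 1.96 * sqrt((k/N) / (N * (1 - k/N)))`.
#' Concentration in copies/uL is `lambda_hat / droplet_volume * dilution`.
#'
#' @param k positive droplets.
#' @param N total droplets.
#' @param droplet_volume droplet volume in uL.
#' @param dilution dilution factor.
#' @param conf confidence level (normal quantile; default 0.95).
#' @param exact use exact binomial (Clopper-Pearson) interval on `k/N`
#'   transformed to the lambda scale instead of the delta method.
#' @return object of class `conc_estimate` with `lambda_hat`,
#'   `copies_per_ul`, `se_lambda`, `ci95` (lambda scale),
#'   `ci95_copies_per_ul`, `k`, `N`.
#' @export
poisson_concentration <- function(k, N, droplet_volume = 8.5e-4,
                                  dilution = 1, conf = 0.95, exact = FALSE) {
  if (N == 0) stop_dq("empty run: N = 0 droplets", "empty_run")
  if (k < 0 || k > N) stop_dq("k must satisfy 0 <= k <= N", "bad_counts")
  if (k == N) stop_dq("saturated run: every droplet positive", "saturated_run")
  p <- k / N
  lambda <- -log1p(-p)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (exact) {
    bt <- stats::binom.test(k, N, conf.level = conf)
    ci <- -log1p(-as.numeric(bt$conf.int))
  } else {
    se <- sqrt(p / (N * (1 - p)))
    ci <- lambda + c(-1, 1) * z * se
  }
  se <- sqrt(p / (N * (1 - p)))
  scale <- dilution / droplet_volume
  structure(list(lambda_hat = lambda, copies_per_ul = lambda * scale,
                 se_lambda = se, ci95 = ci,
                 ci95_copies_per_ul = ci * scale,
                 k = as.integer(k), N = as.integer(N),
                 droplet_volume = droplet_volume, dilution = dilution),
            class = "conc_estimate")
}

#' @export
print.conc_estimate <- function(x, ...) {
  cat(sprintf("<conc_estimate> lambda=%.4f (%d/%d), %.1f copies/uL [%.1f, %.1f]\n",
              x$lambda_hat, x$k, x$N, x$copies_per_ul,
              x$ci95_copies_per_ul[1], x$ci95_copies_per_ul[2]))
  invisible(x)
}

#' Concentration estimates for all assays of a gated run
#'
#' @param g a `gated_counts` object.
#' @param ... passed to [poisson_concentration()].
#' @return named list of `conc_estimate`s.
#' @export
run_concentrations <- function(g, ...) {
  stopifnot(inherits(g, "gated_counts"))
  out <- lapply(seq_len(nrow(g)), function(i)
    poisson_concentration(g$k[i], g$N[i],
                          droplet_volume = attr(g, "droplet_volume"),
                          dilution = attr(g, "dilution") %||% 1, ...))
  names(out) <- g$assay
  out
}

conc_value <- function(x) if (inherits(x, "conc_estimate")) x$copies_per_ul else as.numeric(x)
conc_se <- function(x) {
  if (inherits(x, "conc_estimate"))
    x$se_lambda * x$dilution / x$droplet_volume
  else NA_real_
}

#' Vector copy number by reference-locus normalization
#'
#' `vcn = ploidy * target / titin` vector genomes per diploid host genome,
#' the ratio with the Titin amplification; the diploid reference carries
#' two Titin copies per genome, hence the default ploidy factor 2.
#'
#' @param target,titin concentrations (numbers in copies/uL, or
#'   `conc_estimate`s for CI propagation).
#' @param ploidy copies of the reference locus per host genome.
#' @return object of class `ratio_estimate` (value + 95% CI when the
#'   inputs carry uncertainty).
#' @export
vcn <- function(target, titin, ploidy = 2) {
  tt <- conc_value(titin)
  if (tt == 0) stop_dq("zero reference: Titin concentration is 0", "zero_reference")
  ratio_estimate(ploidy * conc_value(target) / tt,
                 rel_var(target) + rel_var(titin))
}

rel_var <- function(x) {
  v <- conc_value(x); s <- conc_se(x)
  if (is.na(s) || v == 0) 0 else (s / v)^2
}

ratio_estimate <- function(value, relvar) {
  se <- abs(value) * sqrt(relvar)
  structure(list(value = value, se = se,
                 ci95 = value + c(-1, 1) * stats::qnorm(0.975) * se),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%.4g [%.4g, %.4g]\n", x$value, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Homologous-recombination efficiency
#'
#' Efficiency of transgene reconstitution: copies/uL of the recombined
#' region divided by the copies/uL of the limiting (less abundant) single
#' vector, as a percentage. The limiting vector determines the overall
#' possibilities of recombination. The 95% CI propagates counting error of
#' both concentrations by the ratio delta method. Inputs must come from a
#' SmaI-pre-digested run (head-to-tail concatemers are otherwise
#' indistinguishable from recombined molecules and inflate the estimate).
#'
#' @param rec recombined-assay concentration (number or `conc_estimate`).
#' @param c5,c3 single-vector concentrations.
#' @return `ratio_estimate`, value in percent.
#' @export
hr_efficiency <- function(rec, c5, c3) {
  v5 <- conc_value(c5); v3 <- conc_value(c3)
  lim <- if (v5 <= v3) c5 else c3
  vl <- min(v5, v3)
  if (vl == 0) stop_dq("undefined efficiency: limiting vector concentration is 0",
                       "zero_reference")
  ratio_estimate(100 * conc_value(rec) / vl, rel_var(rec) + rel_var(lim))
}

#' ITR-concatemer fraction
#'
#' Sum of junction-assay concentrations divided by the sum of 5' + 3'
#' single-vector concentrations, as a percentage, from an AleI-digested
#' run. `poisson_correct = FALSE` uses raw positive-droplet counts instead
#' of Poisson-corrected copies (the raw-droplet variant of the same
#' fraction).
#'
#' @param junctions single multiplexed junction concentration or vector /
#'   list of per-reaction concentrations (numbers or `conc_estimate`s).
#' @param c5,c3 single-vector concentrations.
#' @param poisson_correct use Poisson-corrected concentrations (default)
#'   or raw positive-droplet counts (requires `conc_estimate` inputs).
#' @return `ratio_estimate`, value in percent.
#' @export
concatemer_fraction <- function(junctions, c5, c3, poisson_correct = TRUE) {
  if (inherits(junctions, "conc_estimate")) junctions <- list(junctions)
  if (!is.list(junctions)) junctions <- as.list(junctions)
  if (poisson_correct) {
    jx <- sum(vapply(junctions, conc_value, numeric(1)))
    den <- conc_value(c5) + conc_value(c3)
    if (den == 0) stop_dq("5' + 3' concentration is 0", "zero_reference")
    jvar <- sum(vapply(junctions, function(x) {
      s <- conc_se(x); if (is.na(s)) 0 else s^2
    }, numeric(1)))
    dvar <- sum(vapply(list(c5, c3), function(x) {
      s <- conc_se(x); if (is.na(s)) 0 else s^2
    }, numeric(1)))
    relvar <- (if (jx > 0) jvar / jx^2 else 0) + dvar / den^2
    ratio_estimate(100 * jx / den, relvar)
  } else {
    kj <- sum(vapply(junctions, function(x) {
      if (!inherits(x, "conc_estimate"))
        stop_dq("raw-droplet variant needs conc_estimate inputs", "bad_counts")
      x$k
    }, numeric(1)))
    kd <- c5$k + c3$k
    if (kd == 0) stop_dq("no positive 5'/3' droplets", "zero_reference")
    ratio_estimate(100 * kj / kd, 0)
  }
}

#' Expression-specificity profile
#'
#' Concentrations of the class-specific RT assays (full recombined
#' message, premature 5'-vector leak, aberrant 3' transcript) plus a
#' verdict: expression is `"specific"` iff the 3' signal is below
#' `three_max_frac` of the recombined signal and the 5' leak below
#' `five_max_frac` of it. A minus-RT control above
#' `contamination_max_frac` of the recombined signal raises a
#' genomic-contamination error.
#'
#' @param rt named concentrations (list of `conc_estimate`s or numeric)
#'   with entries `REC_RT`, `FIVE_RT`, `THREE_RT`.
#' @param minus_rt positive count or concentration of the minus-RT control
#'   (default 0).
#' @param three_max_frac,five_max_frac,contamination_max_frac thresholds
#'   as fractions of the recombined concentration.
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(rt, minus_rt = 0, three_max_frac = 0.01,
                               five_max_frac = 0.1,
                               contamination_max_frac = 0.01) {
  need <- c("REC_RT", "FIVE_RT", "THREE_RT")
  if (!all(need %in% names(rt)))
    stop_dq("rt must name REC_RT, FIVE_RT, THREE_RT", "bad_counts")
  v <- vapply(rt[need], conc_value, numeric(1))
  mrt <- conc_value(minus_rt)
  if (v["REC_RT"] > 0 && mrt > contamination_max_frac * v["REC_RT"])
    stop_dq("minus-RT control positive: genomic DNA contamination",
            "genomic_contamination")
  specific <- (v["REC_RT"] > 0) &&
    (v["THREE_RT"] <= three_max_frac * v["REC_RT"]) &&
    (v["FIVE_RT"] <= five_max_frac * v["REC_RT"])
  structure(list(concentrations = v, minus_rt = mrt,
                 specific = specific,
                 thresholds = c(three_max_frac = three_max_frac,
                                five_max_frac = five_max_frac)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> REC=%.1f FIVE=%.1f THREE=%.1f copies/uL -> %s\n",
              x$concentrations["REC_RT"], x$concentrations["FIVE_RT"],
              x$concentrations["THREE_RT"],
              if (x$specific) "specific" else "not specific"))
  invisible(x)
}

#' Assemble the quantification report
#'
#' Combines a SmaI-digested VCN/REC run, an AleI-digested junction run and
#' (optionally) RT runs into one report: per-assay concentrations, VCNs,
#' HR efficiency (%), concatemer fraction (%), the HR/concatemer fold
#' ratio, and the expression profile. Digestion labels on the gated inputs
#' are checked against the protocol (REC/VCN needs SmaI; junctions need
#' AleI); a mismatch is an error unless `allow_protocol_mismatch` is set,
#' in which case the report is flagged instead (running the mismatched
#' protocol demonstrates the head-to-tail bias the digestion removes).
#'
#' @param smai_run `gated_counts` of the SmaI reaction (FIVE/THREE/REC/TTN).
#' @param alei_run `gated_counts` of the AleI junction reaction (junction
#'   assays plus FIVE/THREE for the denominator).
#' @param rt_run optional `gated_counts` of the RT reaction.
#' @param minus_rt_run optional `gated_counts` of the minus-RT control.
#' @param ploidy reference copies per genome for VCN.
#' @param allow_protocol_mismatch flag instead of erroring on digestion
#'   mismatches.
#' @return object of class `quant_report`.
#' @export
quant_report <- function(smai_run, alei_run = NULL, rt_run = NULL,
                         minus_rt_run = NULL, ploidy = 2,
                         allow_protocol_mismatch = FALSE) {
  flags <- character(0)
  chk <- function(run, want, what) {
    dg <- attr(run, "digestion")
    if (!identical(dg, want)) {
      msg <- sprintf("%s run declares digestion '%s' (expected '%s')",
                     what, dg %||% NA, want)
      if (allow_protocol_mismatch) flags <<- c(flags, msg)
      else stop_dq(paste("protocol mismatch:", msg), "protocol_mismatch")
    }
  }
  chk(smai_run, "SmaI", "VCN/REC")
  conc <- run_concentrations(smai_run)
  need <- c("FIVE", "THREE", "REC", "TTN")
  if (!all(need %in% names(conc)))
    stop_dq("SmaI run must carry FIVE, THREE, REC, TTN assays", "bad_counts")
  vcn5 <- vcn(conc$FIVE, conc$TTN, ploidy)
  vcn3 <- vcn(conc$THREE, conc$TTN, ploidy)
  vcn_rec <- vcn(conc$REC, conc$TTN, ploidy)
  hr <- hr_efficiency(conc$REC, conc$FIVE, conc$THREE)

  concat <- NULL; fold <- NULL; conc_j <- NULL
  if (!is.null(alei_run)) {
    chk(alei_run, "AleI", "junction")
    conc_j <- run_concentrations(alei_run)
    jx <- conc_j[grepl("^jx", names(conc_j))]
    if (!length(jx) || !all(c("FIVE", "THREE") %in% names(conc_j)))
      stop_dq("AleI run must carry junction assays plus FIVE and THREE",
              "bad_counts")
    concat <- concatemer_fraction(jx, conc_j$FIVE, conc_j$THREE)
    fold <- if (concat$value > 0) hr$value / concat$value else Inf
    if (!is.finite(fold)) flags <- c(flags, "no concatemer signal: fold ratio infinite")
  }

  expr <- NULL
  if (!is.null(rt_run)) {
    conc_rt <- run_concentrations(rt_run)
    mrt <- if (!is.null(minus_rt_run)) {
      cm <- run_concentrations(minus_rt_run)
      sum(vapply(cm, conc_value, numeric(1)))
    } else 0
    expr <- expression_profile(conc_rt, minus_rt = mrt)
  }
  structure(list(conc = conc, conc_junction = conc_j,
                 vcn5 = vcn5, vcn3 = vcn3, vcn_rec = vcn_rec,
                 hr_pct = hr, concat_pct = concat,
                 fold_hr_over_concat = fold,
                 expression = expr, flags = flags),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("Dual-AAV ddPCR quantification report\n")
  cat(sprintf("  VCN 5': %.2f   VCN 3': %.2f   VCN rec: %.2f (vg/diploid genome)\n",
              x$vcn5$value, x$vcn3$value, x$vcn_rec$value))
  cat(sprintf("  HR efficiency: %.1f%% [%.1f, %.1f]\n",
              x$hr_pct$value, x$hr_pct$ci95[1], x$hr_pct$ci95[2]))
  if (!is.null(x$concat_pct))
    cat(sprintf("  Concatemer fraction: %.2f%% [%.2f, %.2f]   HR/concat fold: %.1f\n",
                x$concat_pct$value, x$concat_pct$ci95[1], x$concat_pct$ci95[2],
                x$fold_hr_over_concat))
  if (!is.null(x$expression))
    print(x$expression)
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' @export
summary.quant_report <- function(object, ...) {
  print(object)
  cat("  per-assay copies/uL (SmaI run):\n")
  for (nm in names(object$conc))
    cat(sprintf("    %-6s %8.2f [%6.2f, %6.2f]\n", nm,
                object$conc[[nm]]$copies_per_ul,
                object$conc[[nm]]$ci95_copies_per_ul[1],
                object$conc[[nm]]$ci95_copies_per_ul[2]))
  invisible(object)
}

#' @export
coef.quant_report <- function(object, ...) {
  c(vcn5 = object$vcn5$value, vcn3 = object$vcn3$value,
    vcn_rec = object$vcn_rec$value, hr_pct = object$hr_pct$value,
    concat_pct = if (!is.null(object$concat_pct)) object$concat_pct$value else NA_real_,
    fold_hr_over_concat = object$fold_hr_over_concat %||% NA_real_)
}

#' Serialize a report
#' @param x a `quant_report`.
#' @param path JSON output path.
#' @export
write_report_json <- function(x, path) {
  ser <- function(r) if (is.null(r)) NULL else list(value = r$value, ci95 = r$ci95)
  obj <- list(
    vcn5 = ser(x$vcn5), vcn3 = ser(x$vcn3), vcn_rec = ser(x$vcn_rec),
    hr_pct = ser(x$hr_pct), concat_pct = ser(x$concat_pct),
    fold_hr_over_concat = x$fold_hr_over_concat,
    conc = lapply(x$conc, function(ce)
      list(k = ce$k, N = ce$N, lambda = ce$lambda_hat,
           copies_per_ul = ce$copies_per_ul)),
    conc_junction = lapply(x$conc_junction, function(ce)
      list(k = ce$k, N = ce$N, lambda = ce$lambda_hat,
           copies_per_ul = ce$copies_per_ul)),
    expression = if (!is.null(x$expression))
      list(concentrations = as.list(x$expression$concentrations),
           specific = x$expression$specific),
    flags = x$flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(path)
}
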