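# In-silico droplet digital PCR: Poisson partitioning of fragment classes
# into droplets, per-fragment assay evaluation, amplitude-cloud generation
# for probe-concentration multiplexing, and gating back to positive counts.

#' ddPCR run configuration
#'
#' Defaults follow standard QX droplet geometry: 20,000 droplets of
#' 0.85 nL from a 20 uL reaction.
#'
#' @param n_droplets number of droplets.
#' @param droplet_volume droplet volume in uL.
#' @param sample_volume reaction volume in uL (molecule counts divided by
#'   this give copies/uL).
#' @param dilution dilution factor applied when reporting copies/uL.
#' @param noise_sd Gaussian amplitude noise SD (amplitude units).
#' @param baseline per-channel baseline amplitude.
#' @param amp_unit amplitude increment per positive level unit.
#' @param seed RNG seed for partitioning and noise.
#' @return object of class `ddpcr_config`.
#' @export
ddpcr_config <- function(n_droplets = 20000L, droplet_volume = 8.5e-4,
                         sample_volume = 20, dilution = 1,
                         noise_sd = 50, baseline = 500, amp_unit = 1000,
                         seed = 1L) {
  if (n_droplets <= 0) stop_dq("n_droplets must be > 0", "empty_run")
  stopifnot(droplet_volume > 0, sample_volume > 0, dilution > 0,
            noise_sd >= 0, amp_unit > 0)
  structure(list(n_droplets = as.integer(n_droplets),
                 droplet_volume = droplet_volume,
                 sample_volume = sample_volume, dilution = dilution,
                 noise_sd = noise_sd, baseline = baseline,
                 amp_unit = amp_unit, seed = as.integer(seed)),
            class = "ddpcr_config")
}

#' Can an assay amplify a fragment?
#'
#' Site-pair assays require both primer sites on the fragment, convergently
#' oriented (forward-type site on one strand upstream of the reverse-type
#' site on the other), with span at most `max_amplicon`; orientation of the
#' whole fragment is immaterial. Junction assays fire when the fragment
#' contains an ITR junction whose flanking outward-primer class belongs to
#' the assay (palindromic junctions are served by a single primer on both
#' sides). RT assays match the fragment's transcript class.
#'
#' @param fragment one fragment record from a `fragment_population`.
#' @param assay an `assay_def`.
#' @return logical scalar.
#' @export
amplifiable <- function(fragment, assay) {
  if (assay$target_class == "transcript")
    return(identical(fragment$transcript_class %||% NA_character_,
                     assay$transcript_class))
  if (assay$target_class == "junction") {
    return(any(fragment$jclass %in% assay$junction_classes))
  }
  is_p <- fragment$kind == "primer"
  fsel <- is_p & fragment$name == assay$fwd
  rsel <- is_p & fragment$name == assay$rev
  if (!any(fsel) || !any(rsel)) return(FALSE)
  conv <- function(pf, pr) {
    # forward-type site upstream of reverse-type site, within max_amplicon
    d <- outer(pr, pf, `-`)
    any(d > 0 & d <= assay$max_amplicon)
  }
  fp <- fragment$pos[fsel & fragment$strand == "+"]
  rm_ <- fragment$pos[rsel & fragment$strand == "-"]
  fm <- fragment$pos[fsel & fragment$strand == "-"]
  rp <- fragment$pos[rsel & fragment$strand == "+"]
  (length(fp) && length(rm_) && conv(fp, rm_)) ||
    (length(rp) && length(fm) && conv(rp, fm))
}

# Assay-by-fragment-class amplifiability matrix.
amp_matrix <- function(f, panel) {
  vapply(panel$assays, function(a)
    vapply(f$fragments, amplifiable, logical(1), assay = a),
    logical(length(f$fragments)))
}

#' Partition fragments into droplets
#'
#' Each fragment class loads droplets independently with occupancy
#' `Poisson(lambda_i)`, `lambda_i = c_i * droplet_volume`, where `c_i` is
#' the class concentration `count_i / sample_volume`.
#'
#' @param f a `fragment_population`.
#' @param cfg a [ddpcr_config()].
#' @return object of class `droplet_occupancy`: integer matrix
#'   `n_droplets x n_classes` plus the per-class lambdas.
#' @export
partition_fragments <- function(f, cfg) {
  stopifnot(inherits(f, "fragment_population"), inherits(cfg, "ddpcr_config"))
  lambda <- f$counts / cfg$sample_volume * cfg$droplet_volume
  if (any(lambda > 10))
    stop_dq(sprintf("saturated run: class lambda %.2f exceeds 10 (mis-scaled input?)",
                    max(lambda)), "saturated_run")
  set.seed(cfg$seed)
  N <- cfg$n_droplets
  occ <- if (length(lambda))
    matrix(stats::rpois(N * length(lambda), rep(lambda, each = N)),
           nrow = N)
  else matrix(0L, nrow = N, ncol = 0)
  structure(list(occupancy = occ, lambda = lambda, fragments = f,
                 cfg = cfg), class = "droplet_occupancy")
}

#' Evaluate assays over droplets
#'
#' Calls mode: a droplet is positive for an assay iff it contains at least
#' one fragment the assay can amplify (exact boolean per assay). Amplitude
#' mode: per channel, amplitude = baseline + amp_unit * sum of levels of
#' the assays positive in the droplet + Gaussian noise, producing the
#' multiplexed cloud grid; requires a probe panel with at most one assay
#' per (channel, level) and levels in {1, 2}.
#'
#' @param occ a `droplet_occupancy`.
#' @param panel an `assay_panel`.
#' @param mode `"calls"` or `"amplitude"`.
#' @return object of class `droplet_dataset`.
#' @export
detect_droplets <- function(occ, panel, mode = c("calls", "amplitude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(occ, "droplet_occupancy"), inherits(panel, "assay_panel"))
  A <- amp_matrix(occ$fragments, panel)
  if (is.null(dim(A))) A <- matrix(A, nrow = length(occ$fragments$fragments))
  N <- occ$cfg$n_droplets
  pos <- matrix(FALSE, N, length(panel$assays),
                dimnames = list(NULL, names(panel$assays)))
  for (a in seq_along(panel$assays)) {
    sel <- which(A[, a])
    if (length(sel))
      pos[, a] <- rowSums(occ$occupancy[, sel, drop = FALSE]) > 0
  }
  if (mode == "calls") {
    return(structure(list(mode = "calls", calls = pos, n_droplets = N,
                          cfg = occ$cfg, panel_names = names(panel$assays)),
                     class = "droplet_dataset"))
  }
  chans <- vapply(panel$assays, `[[`, character(1), "channel")
  levels <- vapply(panel$assays, `[[`, numeric(1), "level")
  if (any(chans == "single"))
    stop_dq("amplitude mode requires a probe (FAM/VIC) panel", "amplitude_panel")
  for (ch in unique(chans)) {
    lv <- levels[chans == ch]
    if (anyDuplicated(lv) || !all(lv %in% c(1, 2)))
      stop_dq("amplitude mode needs distinct levels in {1,2} per channel",
              "amplitude_panel")
  }
  set.seed(occ$cfg$seed + 1L)  # noise substream
  amp <- matrix(occ$cfg$baseline, N, 2, dimnames = list(NULL, c("FAM", "VIC")))
  for (a in seq_along(panel$assays)) {
    ch <- chans[a]
    amp[, ch] <- amp[, ch] + occ$cfg$amp_unit * levels[a] * pos[, a]
  }
  if (occ$cfg$noise_sd > 0)
    amp <- amp + matrix(stats::rnorm(2 * N, 0, occ$cfg$noise_sd), N, 2)
  structure(list(mode = "amplitude", amplitudes = amp, n_droplets = N,
                 cfg = occ$cfg, panel_names = names(panel$assays),
                 channels = chans, levels = levels),
            class = "droplet_dataset")
}

#' @export
print.droplet_dataset <- function(x, ...) {
  cat(sprintf("<droplet_dataset> %s mode, %d droplets, assays: %s\n",
              x$mode, x$n_droplets, paste(x$panel_names, collapse = ", ")))
  invisible(x)
}

#' Gate droplets into per-assay positive counts
#'
#' Calls mode: pass-through column sums. Amplitude mode: per channel,
#' strictly increasing thresholds between consecutive cloud levels decode
#' each droplet's level (0..3); level bit 1 marks the level-1 assay
#' positive, bit 2 the level-2 assay.
#'
#' @param d a `droplet_dataset`.
#' @param panel the `assay_panel` used for detection (needed in amplitude
#'   mode to map levels back to assays).
#' @param thresholds named list of per-channel threshold vectors
#'   (amplitude mode); defaults to midpoints between cloud centers.
#' @param digestion optional label (`"SmaI"`, `"AleI"`, `"none"`) recorded
#'   for downstream protocol checks.
#' @return object of class `gated_counts`: data.frame `assay`, `k`, `N`
#'   with the run configuration attached.
#' @export
gate_droplets <- function(d, panel = NULL, thresholds = NULL,
                          digestion = NA_character_) {
  stopifnot(inherits(d, "droplet_dataset"))
  if (d$mode == "calls") {
    k <- colSums(d$calls)
    res <- data.frame(assay = colnames(d$calls), k = as.integer(k),
                      N = d$n_droplets, row.names = NULL)
  } else {
    if (is.null(panel)) stop_dq("amplitude gating needs the assay panel", "gating")
    if (is.null(thresholds)) {
      ctr <- d$cfg$baseline + d$cfg$amp_unit * (0:3)
      thr <- (ctr[-1] + ctr[-4]) / 2
      thresholds <- list(FAM = thr, VIC = thr)
    }
    for (ch in names(thresholds))
      if (is.unsorted(thresholds[[ch]], strictly = TRUE))
        stop_dq("thresholds must be strictly increasing", "gating")
    chans <- d$channels
    levs <- d$levels
    if (is.null(chans)) {
      aa <- panel$assays[unlist(d$panel_names)]
      chans <- vapply(aa, `[[`, character(1), "channel")
      levs <- vapply(aa, `[[`, numeric(1), "level")
    }
    k <- integer(length(d$panel_names)); names(k) <- d$panel_names
    for (ch in c("FAM", "VIC")) {
      idx <- which(chans == ch)
      if (!length(idx)) next
      lev <- findInterval(d$amplitudes[, ch], thresholds[[ch]])
      for (a in idx) {
        bit <- as.integer(levs[a])
        k[a] <- sum(bitwAnd(pmin(lev, 3L), bit) == bit)
      }
    }
    res <- data.frame(assay = d$panel_names, k = as.integer(k),
                      N = d$n_droplets, row.names = NULL)
  }
  structure(res, class = c("gated_counts", "data.frame"),
            droplet_volume = d$cfg$droplet_volume,
            sample_volume = d$cfg$sample_volume,
            dilution = d$cfg$dilution,
            digestion = digestion)
}

#' Write droplet data as QX-style CSV
#'
#' Amplitude mode: columns `Ch1 Amplitude`, `Ch2 Amplitude`. Calls mode:
#' one 0/1 column per assay. Run metadata (mode, droplet count, assays,
#' droplet/sample volume, digestion, seed) goes to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param d a `droplet_dataset`.
#' @param path CSV path.
#' @param digestion digestion label stored in the sidecar.
#' @export
write_droplet_csv <- function(d, path, digestion = NA_character_) {
  stopifnot(inherits(d, "droplet_dataset"))
  if (d$mode == "amplitude") {
    df <- data.frame(`Ch1 Amplitude` = d$amplitudes[, "FAM"],
                     `Ch2 Amplitude` = d$amplitudes[, "VIC"],
                     check.names = FALSE)
  } else {
    df <- as.data.frame(d$calls + 0L)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(mode = d$mode, n_droplets = d$n_droplets,
               assays = as.list(d$panel_names),
               droplet_volume = d$cfg$droplet_volume,
               sample_volume = d$cfg$sample_volume,
               dilution = d$cfg$dilution,
               digestion = digestion, seed = d$cfg$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a droplet CSV written by [write_droplet_csv()]
#'
#' @param path CSV path (the `.meta.json` sidecar must sit alongside).
#' @return a `droplet_dataset`.
#' @export
read_droplet_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop_dq(paste("missing metadata sidecar", meta_path), "parse_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop_dq(paste("malformed CSV:", conditionMessage(e)),
                           "parse_error"))
  cfg <- ddpcr_config(n_droplets = meta$n_droplets,
                      droplet_volume = meta$droplet_volume,
                      sample_volume = meta$sample_volume,
                      dilution = meta$dilution %||% 1,
                      seed = meta$seed %||% 1L)
  if (identical(meta$mode, "amplitude")) {
    need <- c("Ch1 Amplitude", "Ch2 Amplitude")
    if (!all(need %in% names(df)))
      stop_dq("amplitude CSV must have Ch1/Ch2 Amplitude columns", "parse_error")
    amp <- as.matrix(df[, need]); colnames(amp) <- c("FAM", "VIC")
    if (any(!is.finite(amp)))
      stop_dq(sprintf("non-finite amplitude at row %d",
                      which(!is.finite(rowSums(amp)))[1]), "parse_error")
    structure(list(mode = "amplitude", amplitudes = amp,
                   n_droplets = nrow(df), cfg = cfg,
                   panel_names = meta$assays,
                   channels = NULL, levels = NULL,
                   digestion = meta$digestion),
              class = "droplet_dataset")
  } else {
    bad <- !vapply(df, function(v) all(v %in% c(0, 1)), logical(1))
    if (any(bad))
      stop_dq(sprintf("non-boolean call column '%s'", names(df)[bad][1]),
              "parse_error")
    structure(list(mode = "calls", calls = as.matrix(df) > 0,
                   n_droplets = nrow(df), cfg = cfg,
                   panel_names = names(df),
                   digestion = meta$digestion),
              class = "droplet_dataset")
  }
}
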