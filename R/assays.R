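# Assay panel: primer binding sites at coordinate level plus detection
# chemistry. Probe (TaqMan-style) assays carry a channel (FAM/VIC) and an
# amplitude level used for probe-concentration multiplexing; intercalating
# (EvaGreen-style) assays are single-channel. Junction assays are defined
# by the pair of outward-facing primers that flank an ITR-ITR junction.

#' Define one ddPCR assay
#'
#' @param name assay name.
#' @param chemistry `"probe"` or `"intercalating"`.
#' @param channel `"FAM"`, `"VIC"` (probe) or `"single"` (intercalating).
#' @param level positive amplitude multiplier used for cloud multiplexing.
#' @param max_amplicon maximum amplifiable span in bp.
#' @param target_class one of `"five_unique"`, `"three_unique"`,
#'   `"recombined"`, `"junction"`, `"host_reference"`, `"transcript"`.
#' @param fwd,rev primer names (site-pair assays).
#' @param junction_classes character vector of flanking-primer junction
#'   classes detected (junction assays), e.g. `"A|B"`.
#' @param transcript_class transcript class detected (RT assays).
#' @return object of class `assay_def`.
#' @export
assay_def <- function(name, chemistry, channel, level, max_amplicon,
                      target_class, fwd = NULL, rev = NULL,
                      junction_classes = NULL, transcript_class = NULL) {
  chemistry <- match.arg(chemistry, c("probe", "intercalating"))
  channel <- match.arg(channel, c("FAM", "VIC", "single"))
  if (chemistry == "probe" && channel == "single")
    stop_dq("probe assays need channel FAM or VIC", "assay_invalid")
  if (chemistry == "intercalating" && channel != "single")
    stop_dq("intercalating assays are single-channel", "assay_invalid")
  structure(list(name = name, chemistry = chemistry, channel = channel,
                 level = level, max_amplicon = max_amplicon,
                 target_class = target_class, fwd = fwd, rev = rev,
                 junction_classes = junction_classes,
                 transcript_class = transcript_class),
            class = "assay_def")
}

# Outward-facing primer at a given unit end. A = 5' tail, C = 5' head,
# D = 3' tail, B = 3' head. Primers A and B bind inside the shared overlap
# (so they sit on both constructs); C and D bind unique ends.
end_primer <- function(identity, end) {
  key <- paste(substr(identity, 1, 4), end)
  switch(key,
         "five tail" = "A", "five head" = "C",
         "thre tail" = "D", "thre head" = "B",
         stop_dq(paste("unknown unit end", key), "internal"))
}

junction_class_label <- function(p1, p2) paste(sort(c(p1, p2)), collapse = "|")

# Junction classes claimed by each of the four single-pair reactions.
# The four reactions target the four cross-vector junction geometries;
# palindromic same-primer junctions (tail-tail / head-head flips of one
# vector with itself) self-amplify in the reaction carrying that primer and
# are attributed to the dual-primer reaction designed for that side.
# Same-identity head-to-tail junctions (classes A|C and B|D) are invisible
# to all four reactions: no reaction contains both required primers.
JX_CLASS_MAP <- list(
  jxAB = c("A|B", "A|A", "B|B"),
  jxCD = c("C|D", "C|C", "D|D"),
  jxAD = c("A|D"),
  jxCB = c("B|C")
)

#' All junction classes detectable by the default junction panel
#' @return character vector of flanking-primer class labels.
#' @export
detectable_junction_classes <- function() unname(unlist(JX_CLASS_MAP))

#' Default assay panel for the dual-vector design
#'
#' Builds the full panel: `FIVE` and `THREE` (single-vector assays with both
#' primers inside the respective unique regions), `REC` (forward primer in
#' the 5'-unique region just upstream of the overlap, reverse in the
#' 3'-unique region just downstream, so only a molecule carrying the whole
#' reconstituted overlap amplifies; intact amplicon 900 bp), `TTN` (diploid
#' host reference), the junction panel `jxAB`/`jxCD`/`jxAD`/`jxCB`
#' (EvaGreen, primers A/B close to the overlap-proximal ITRs and C/D at the
#' opposite ends, with A placed after B inside the overlap so that a pure
#' homologous-recombination molecule yields no junction amplicon), and RT
#' variants of FIVE/THREE/REC for transcript quantification.
#'
#' Probe multiplexing defaults: FIVE = FAM x1, THREE = FAM x2, REC = VIC x1,
#' TTN = VIC x2.
#'
#' @param c5,c3 the two constructs from [build_default_constructs()].
#' @param max_amplicon genomic assay span limit (default 2500 bp; long
#'   enough that an undigested head-to-tail dimer is REC-amplifiable, which
#'   is the reason for SmaI pre-digestion).
#' @param max_amplicon_rt transcript assay span limit (default 250 bp).
#' @return object of class `assay_panel`: list of `assay_def`s plus the
#'   primer site table (`primers` attribute).
#' @export
default_assay_panel <- function(c5, c3, max_amplicon = 2500, max_amplicon_rt = 250) {
  stopifnot(inherits(c5, "aav_construct"), inherits(c3, "aav_construct"))
  ov5 <- c5$overlap; ov3 <- c3$overlap
  # REC primers must flank the whole overlap and give a 900 bp amplicon on
  # the intact recombined molecule: (ov5[2]-fwd) + (rev-ov3[2]) = 900.
  rec_f <- ov5[1] - 50L
  rec_r <- ov3[2] + 900L - (ov5[2] - rec_f)
  if (rec_f <= 0 || rec_r >= c3$length - 145L)
    stop_dq("REC primers cannot be placed to span the whole overlap", "assay_invalid")

  primers <- data.frame(
    primer = c("FIVE_F", "FIVE_R", "THREE_F", "THREE_R", "REC_F", "REC_R",
               "TTN_F", "TTN_R",
               "A", "A", "B", "B", "C", "D"),
    construct = c("five_prime", "five_prime", "three_prime", "three_prime",
                  "five_prime", "three_prime", "host", "host",
                  "five_prime", "three_prime", "five_prime", "three_prime",
                  "five_prime", "three_prime"),
    pos = c(1600L, 1750L, 1100L, 1250L, rec_f, rec_r, 100L, 220L,
            ov5[1] + 780L, ov3[1] + 780L, ov5[1] + 20L, ov3[1] + 20L,
            160L, 2595L),
    strand = c("+", "-", "+", "-", "+", "-", "+", "-",
               "+", "+", "-", "-", "-", "+"),
    stringsAsFactors = FALSE)

  assays <- list(
    assay_def("FIVE", "probe", "FAM", 1, max_amplicon, "five_unique",
              fwd = "FIVE_F", rev = "FIVE_R"),
    assay_def("THREE", "probe", "FAM", 2, max_amplicon, "three_unique",
              fwd = "THREE_F", rev = "THREE_R"),
    assay_def("REC", "probe", "VIC", 1, max_amplicon, "recombined",
              fwd = "REC_F", rev = "REC_R"),
    assay_def("TTN", "probe", "VIC", 2, max_amplicon, "host_reference",
              fwd = "TTN_F", rev = "TTN_R"),
    assay_def("jxAB", "intercalating", "single", 1, max_amplicon, "junction",
              junction_classes = JX_CLASS_MAP$jxAB),
    assay_def("jxCD", "intercalating", "single", 1, max_amplicon, "junction",
              junction_classes = JX_CLASS_MAP$jxCD),
    assay_def("jxAD", "intercalating", "single", 1, max_amplicon, "junction",
              junction_classes = JX_CLASS_MAP$jxAD),
    assay_def("jxCB", "intercalating", "single", 1, max_amplicon, "junction",
              junction_classes = JX_CLASS_MAP$jxCB),
    assay_def("FIVE_RT", "intercalating", "single", 1, max_amplicon_rt,
              "transcript", transcript_class = "five_leak"),
    assay_def("THREE_RT", "intercalating", "single", 1, max_amplicon_rt,
              "transcript", transcript_class = "three_aberrant"),
    assay_def("REC_RT", "intercalating", "single", 1, max_amplicon_rt,
              "transcript", transcript_class = "recombined")
  )
  names(assays) <- vapply(assays, `[[`, character(1), "name")
  structure(list(assays = assays, primers = primers),
            class = "assay_panel")
}

#' Subset an assay panel by assay names
#' @param panel an `assay_panel`.
#' @param names character vector of assay names to keep.
#' @export
panel_subset <- function(panel, names) {
  stopifnot(inherits(panel, "assay_panel"))
  missing <- setdiff(names, names(panel$assays))
  if (length(missing))
    stop_dq(paste("unknown assays:", paste(missing, collapse = ", ")), "assay_invalid")
  structure(list(assays = panel$assays[names], primers = panel$primers),
            class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("<assay_panel> %d assays: %s\n", length(x$assays),
              paste(names(x$assays), collapse = ", ")))
  invisible(x)
}
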