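# Shared fixtures, built in code. Constructs and the default panel are
# deterministic, so they are computed once per test run.

dq_constructs <- local({
  cs <- NULL
  function() {
    if (is.null(cs)) cs <<- build_default_constructs()
    cs
  }
})

dq_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) {
      cs <- dq_constructs()
      p <<- default_assay_panel(cs$five_prime, cs$three_prime)
    }
    p
  }
})

# Single-species population shortcut.
pop1 <- function(structure, count = 1L, host_genomes = 0L) {
  sample_population(list(parse_structure(structure, count)), host_genomes)
}

# Independent unit recount from structure strings (oracle for unit
# conservation): counts "5"/"3" unit tokens per species times counts.
recount_units <- function(pop) {
  t5 <- 0L; t3 <- 0L
  for (m in pop$species) {
    s <- structure_string(m)
    units <- regmatches(s, gregexpr("[53][+-]", s))[[1]]
    t5 <- t5 + m$count * sum(substr(units, 1, 1) == "5")
    t3 <- t3 + m$count * sum(substr(units, 1, 1) == "3")
  }
  list(T5 = t5, T3 = t3)
}

# Physical amplification oracle for junction fragments: enumerates every
# convergent same-or-cross primer pair among `primers` over the fragment's
# retained sites, independent of the junction-class bookkeeping.
oracle_pair_amplifiable <- function(fragment, primers, max_amplicon = 2500) {
  is_p <- fragment$kind == "primer" & fragment$name %in% primers
  pos <- fragment$pos[is_p]; strand <- fragment$strand[is_p]
  if (length(pos) < 2) return(FALSE)
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (i == j) next
    if (strand[i] == "+" && strand[j] == "-" &&
        pos[j] > pos[i] && pos[j] - pos[i] <= max_amplicon)
      return(TRUE)
  }
  FALSE
}

# Per-assay positive counts via a fresh detection on a given occupancy.
counts_for_panel <- function(occ, panel, names) {
  g <- gate_droplets(detect_droplets(occ, panel_subset(panel, names),
                                     mode = "calls"))
  stats::setNames(g$k, g$assay)
}
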