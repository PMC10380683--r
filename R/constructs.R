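# Vector construct model: coordinate-level description of the 5' and 3'
# halves of the split quasidystrophin transgene. Coordinates are 0-based,
# half-open; the plus strand is the coding strand of each construct. All
# per-element lengths are stand-ins (the synthesized sequence is
# proprietary); the printed anchors that matter downstream are the 800 bp
# homologous overlap and the 900 bp intact recombined amplicon.

AAV_CAPACITY <- 4700L
ITR_LEN <- 145L

#' Construct a vector-genome description
#'
#' An `aav_construct` is an ordered element map of one AAV genome: inverted
#' terminal repeats (ITRs) at both ends, regulatory and coding elements in
#' between, the homologous overlap interval shared by the two vectors, and
#' the restriction landscape (one SmaI site inside each ITR, exactly one
#' AleI site outside ITRs and overlap).
#'
#' @param identity `"five_prime"` or `"three_prime"`.
#' @param elements data.frame with columns `label`, `start`, `end` tiling
#'   `[0, length)` contiguously.
#' @param overlap length-2 integer vector, 0-based half-open interval of the
#'   homologous region.
#' @param itr list of two length-2 intervals (left and right ITR).
#' @param smaI integer vector of SmaI cut positions, each inside an ITR.
#' @param aleI single AleI cut position, outside ITRs and overlap.
#' @return An object of class `aav_construct`.
#' @export
vector_construct <- function(identity, elements, overlap, itr, smaI, aleI) {
  identity <- match.arg(identity, c("five_prime", "three_prime"))
  elements <- as.data.frame(elements)
  stopifnot(all(c("label", "start", "end") %in% names(elements)))
  x <- structure(list(
    identity = identity,
    length = max(elements$end),
    elements = elements,
    overlap = as.integer(overlap),
    itr = lapply(itr, as.integer),
    smaI = as.integer(smaI),
    aleI = as.integer(aleI)
  ), class = "aav_construct")
  validate_construct(x)
  x
}

#' Validate an `aav_construct`
#'
#' Checks the structural invariants: elements tile the construct without
#' gaps or overlaps, total length within AAV packaging capacity (4700 bp
#' ITR to ITR), every SmaI site inside an ITR, exactly one AleI site
#' outside ITRs and outside the overlap interval.
#'
#' @param x an `aav_construct`.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_construct <- function(x) {
  stopifnot(inherits(x, "aav_construct"))
  el <- x$elements[order(x$elements$start), ]
  if (el$start[1] != 0L || any(el$start[-1] != el$end[-nrow(el)]))
    stop_dq("elements must tile the construct contiguously", "construct_invalid")
  if (x$length > AAV_CAPACITY)
    stop_dq(sprintf("construct length %d exceeds AAV capacity %d", x$length, AAV_CAPACITY),
            "construct_invalid")
  in_itr <- function(p) any(vapply(x$itr, function(iv) p > iv[1] && p < iv[2], logical(1)))
  if (!all(vapply(x$smaI, in_itr, logical(1))))
    stop_dq("every SmaI site must lie within an ITR interval", "construct_invalid")
  if (length(x$aleI) != 1L)
    stop_dq("exactly one AleI site per construct", "construct_invalid")
  if (in_itr(x$aleI) || (x$aleI > x$overlap[1] && x$aleI < x$overlap[2]))
    stop_dq("AleI site must be outside ITRs and outside the overlap", "construct_invalid")
  if (diff(x$overlap) <= 0)
    stop_dq("overlap interval must be non-empty", "construct_invalid")
  invisible(x)
}

#' Default 5' and 3' vector constructs
#'
#' Builds the two halves of the split transgene. The 5' construct carries
#' ITR, the muscle-specific sp512 promoter, a chimeric intron, a Kozak
#' sequence, then the coding block (N-terminal actin-binding domain,
#' Hinge 1, R1--R3, Hinge 2, R8--R9, R16--R17, Hinge 3, partial R20) and
#' the right ITR. The 3' construct carries ITR, the 800 bp homologous
#' region (partial R16, Hinge 3, partial R20), the completion of R20
#' through R24, Hinge 4, the SV40 polyA and the right ITR; it has no
#' promoter, so no full-length expression can initiate from it. The
#' homologous overlap is 800 bp on both constructs with identical content.
#'
#' @return list with components `five_prime` and `three_prime`.
#' @examples
#' cs <- build_default_constructs()
#' diff(cs$five_prime$overlap)  # 800
#' @export
build_default_constructs <- function() {
  el5 <- data.frame(
    label = c("ITR", "sp512_promoter", "chimeric_intron", "kozak", "N_term",
              "hinge1", "R1_R3", "hinge2", "R8_R9", "R16_R17", "hinge3",
              "R20_partial", "ITR"),
    start = c(0L, 145L, 657L, 790L, 800L, 1500L, 1650L, 2600L, 2750L, 3390L,
              4030L, 4180L, 4500L),
    end   = c(145L, 657L, 790L, 800L, 1500L, 1650L, 2600L, 2750L, 3390L,
              4030L, 4180L, 4500L, 4645L))
  c5 <- vector_construct("five_prime", el5,
                         overlap = c(3700L, 4500L),
                         itr = list(c(0L, 145L), c(4500L, 4645L)),
                         smaI = c(72L, 4572L), aleI = 2000L)

  el3 <- data.frame(
    label = c("ITR", "R16_partial", "hinge3", "R20_partial", "R20_completion",
              "R21", "R22", "R23", "R24", "hinge4", "sv40_polyA", "ITR"),
    start = c(0L, 145L, 475L, 625L, 945L, 1045L, 1365L, 1685L, 2005L, 2325L,
              2475L, 2610L),
    end   = c(145L, 475L, 625L, 945L, 1045L, 1365L, 1685L, 2005L, 2325L,
              2475L, 2610L, 2755L))
  c3 <- vector_construct("three_prime", el3,
                         overlap = c(145L, 945L),
                         itr = list(c(0L, 145L), c(2610L, 2755L)),
                         smaI = c(72L, 2682L), aleI = 1900L)
  list(five_prime = c5, three_prime = c3)
}

#' @export
print.aav_construct <- function(x, ...) {
  cat(sprintf("<aav_construct> %s, %d bp, overlap [%d,%d), SmaI @ %s, AleI @ %d\n",
              x$identity, x$length, x$overlap[1], x$overlap[2],
              paste(x$smaI, collapse = ","), x$aleI))
  invisible(x)
}

#' Write construct element annotation as BED-like table
#'
#' Four tab-separated columns: construct identity, start, end, element label.
#'
#' @param construct an `aav_construct`.
#' @param path output file.
#' @export
write_construct_bed <- function(construct, path) {
  stopifnot(inherits(construct, "aav_construct"))
  df <- data.frame(name = construct$identity,
                   start = construct$elements$start,
                   end = construct$elements$end,
                   label = construct$elements$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
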