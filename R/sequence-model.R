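## Strand arithmetic for crRNA / ERA / activator geometry.
##
## Coordinate convention used throughout: spacer positions are 1-based from
## the spacer 5' end. A "5' toehold" is unpaired spacer sequence at the spacer
## 5' end (the side facing the Cas12a PI domain); a "3' toehold" sits at the
## spacer 3' end (Nuc-domain side).

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")
.DNA_OF_RNA_COMP <- c(A = "T", C = "G", G = "C", U = "A")
## transversion partner substitutions used to place deliberate mismatches
.RNA_TRANSVERSION <- c(A = "C", C = "A", G = "U", U = "G")
.DNA_TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")

.splitChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

## TRUE where the (RNA protector, RNA spacer) bases form a Watson-Crick pair
.pairsRnaRna <- function(a, b) .RNA_COMP[b] == a
## TRUE where the (DNA activator, RNA spacer) bases form a Watson-Crick pair
.pairsDnaRna <- function(a, b) .DNA_OF_RNA_COMP[b] == a

#' Design an ERA for a crRNA spacer
#'
#' Returns the RNA protector strand pairing with the spacer everywhere except
#' a single-stranded toehold of `toeholdLength` nt at the chosen spacer end.
#' Deliberate mismatches are introduced at the given spacer positions by
#' substituting the complementary base with its transversion partner
#' (A<->C, G<->U), a deterministic rule that never creates a wobble pair.
#'
#' @param crrna A [CrRNASpec-class].
#' @param direction `"5prime"` or `"3prime"`: which spacer end carries the
#'   toehold.
#' @param toeholdLength Integer nt, `0 <= toeholdLength <= spacer length - 1`.
#' @param eraMismatches Integer spacer positions (inside the paired span) to
#'   mismatch.
#' @return An [ERASpec-class].
#' @examples
#' cr <- CrRNASpec("ACGUACGUACGUACGUACGUAC")
#' designEra(cr, "5prime", 7)
#' @export
designEra <- function(crrna, direction = c("5prime", "3prime"),
                      toeholdLength, eraMismatches = integer(0)) {
  stopifnot(is(crrna, "CrRNASpec"))
  direction <- match.arg(direction)
  L <- spacerLength(crrna)
  toeholdLength <- as.integer(toeholdLength)
  if (toeholdLength < 0L) stop("toeholdLength must be >= 0")
  if (toeholdLength >= L) stop("empty duplex: toehold consumes the spacer")
  span <- if (direction == "5prime") c(toeholdLength + 1L, L)
          else c(1L, L - toeholdLength)
  eraMismatches <- as.integer(eraMismatches)
  if (length(eraMismatches) &&
      (any(eraMismatches < span[1]) || any(eraMismatches > span[2])))
    stop("mismatch outside duplex: position(s) fall in the toehold")
  spc <- .splitChars(crrna@spacer)
  comp <- .RNA_COMP[spc[span[1]:span[2]]]
  if (length(eraMismatches)) {
    idx <- eraMismatches - span[1] + 1L
    comp[idx] <- .RNA_TRANSVERSION[comp[idx]]
  }
  era <- paste(rev(comp), collapse = "")  # antiparallel: written 5'->3'
  ERASpec(era, span, eraMismatches,
          name = sprintf("ERA_%s_t%d", direction, toeholdLength))
}

#' Design an activator for a crRNA spacer
#'
#' Returns the DNA activator complementary to the spacer except for declared
#' terminal deletions (in spacer coordinates) and mismatch positions
#' (substituted with the DNA transversion partner, A<->C, G<->T).
#'
#' @param crrna A [CrRNASpec-class].
#' @param mismatchPositions Integer spacer positions mismatched to the crRNA.
#' @param deletion5p,deletion3p Integer nt of spacer left uncovered at the
#'   spacer 5' / 3' end.
#' @param strandedness `"ss"` or `"ds"`.
#' @return An [ActivatorSpec-class].
#' @export
designActivator <- function(crrna, mismatchPositions = integer(0),
                            deletion5p = 0L, deletion3p = 0L,
                            strandedness = "ss") {
  stopifnot(is(crrna, "CrRNASpec"))
  L <- spacerLength(crrna)
  deletion5p <- as.integer(deletion5p); deletion3p <- as.integer(deletion3p)
  if (deletion5p < 0L || deletion3p < 0L) stop("deletions must be >= 0")
  lo <- 1L + deletion5p; hi <- L - deletion3p
  if (lo > hi) stop("deletions leave no activator-spacer duplex")
  spc <- .splitChars(crrna@spacer)
  comp <- .DNA_OF_RNA_COMP[spc[lo:hi]]
  mismatchPositions <- as.integer(mismatchPositions)
  if (length(mismatchPositions)) {
    if (any(mismatchPositions < lo) || any(mismatchPositions > hi))
      stop("activator mismatch positions must lie in the covered span")
    idx <- mismatchPositions - lo + 1L
    comp[idx] <- .DNA_TRANSVERSION[comp[idx]]
  }
  ActivatorSpec(paste(rev(comp), collapse = ""), strandedness = strandedness,
                mismatchPositions = mismatchPositions,
                deletion5p = deletion5p, deletion3p = deletion3p)
}

#' Derive the duplex layout of a crRNA/ERA/activator triple
#'
#' Computes the strand-displacement geometry: toehold direction (the spacer
#' end left unpaired by the ERA), forward toehold length (unpaired spacer
#' nucleotides at that end that the activator can actually bind, i.e. net of
#' any activator deletion there), reverse toehold length (the activator
#' deletion at the opposite end, as in toehold exchange), branch-migration
#' domain length, and mismatch distances measured from the
#' forward-toehold-proximal end of the branch-migration domain (0 =
#' immediately adjacent to the toehold).
#'
#' @param crrna A [CrRNASpec-class].
#' @param era An [ERASpec-class]; must be complementary to the declared span
#'   apart from its declared mismatches.
#' @param activator An [ActivatorSpec-class]; must cover the spacer except for
#'   its declared deletions, complementary apart from declared mismatches.
#' @return A [DuplexLayout-class].
#' @examples
#' cr <- CrRNASpec("ACGUACGUACGUACGUACGUAC")
#' buildDuplexLayout(cr, designEra(cr, "5prime", 7), designActivator(cr))
#' @export
buildDuplexLayout <- function(crrna, era, activator) {
  stopifnot(is(crrna, "CrRNASpec"), is(era, "ERASpec"),
            is(activator, "ActivatorSpec"))
  L <- spacerLength(crrna)
  span <- era@pairedSpan
  if (span[2] > L) stop("ERA paired span exceeds the spacer")
  unpaired5 <- span[1] - 1L
  unpaired3 <- L - span[2]
  if (unpaired5 > 0L && unpaired3 > 0L)
    stop("ambiguous layout: ERA leaves the spacer unpaired on both ends")

  ## verify ERA complementarity over the span apart from declared mismatches
  spc <- .splitChars(crrna@spacer)
  eraChars <- .splitChars(era@sequence)
  p <- span[1]:span[2]
  j <- span[2] - p + 1L                     # antiparallel index into the ERA
  paired <- .pairsRnaRna(eraChars[j], spc[p])
  declared <- p %in% era@mismatchPositions
  if (any(paired & declared) || any(!paired & !declared))
    stop("sequence/span inconsistency: ERA mismatches differ from declaration")

  ## verify activator coverage/complementarity
  lo <- 1L + activator@deletion5p; hi <- L - activator@deletion3p
  if (length(activator@sequence) != hi - lo + 1L)
    stop("activator does not cover the spacer minus its declared deletions")
  actChars <- .splitChars(activator@sequence)
  pa <- lo:hi
  ja <- hi - pa + 1L
  pairedA <- .pairsDnaRna(actChars[ja], spc[pa])
  declaredA <- pa %in% activator@mismatchPositions
  if (any(pairedA & declaredA) || any(!pairedA & !declaredA))
    stop("sequence/span inconsistency: activator mismatches differ from declaration")

  direction <- if (unpaired5 > 0L) "5prime"
               else if (unpaired3 > 0L) "3prime"
               else "5prime"               # full-span ERA: no toehold, f = 0
  if (direction == "5prime") {
    f <- max(0L, unpaired5 - activator@deletion5p)
    r <- activator@deletion3p
  } else {
    f <- max(0L, unpaired3 - activator@deletion3p)
    r <- activator@deletion5p
  }
  bm <- span[2] - span[1] + 1L
  dist <- function(pos) {
    if (direction == "5prime") pos - span[1] else span[2] - pos
  }
  layout <- DuplexLayout(direction, f, bm, L, toeholdLengthR = r,
                         bmStart = span[1],
                         eraMismatchDistances = dist(era@mismatchPositions),
                         dsActivator = activator@strandedness == "ds")
  actIn <- activator@mismatchPositions[
    activator@mismatchPositions >= span[1] &
      activator@mismatchPositions <= span[2]]
  if (length(actIn) != length(activator@mismatchPositions))
    stop("position in toehold: activator mismatch outside the bm domain")
  layout@activatorMismatchDistances <- as.integer(sort(dist(actIn)))
  validObject(layout)
  layout
}

#' Distance of a spacer position from the forward toehold
#'
#' Maps a spacer position inside the branch-migration domain to its distance
#' from the forward-toehold-proximal bm boundary (0-based). For a 3'-toehold
#' layout the same offset within the bm domain (counted from its 5' end)
#' yields the complementary distance `bmLength - 1 - d` of the 5'-toehold
#' case, since the proximal boundary switches ends.
#'
#' @param layout A [DuplexLayout-class].
#' @param spacerPosition 1-based spacer position.
#' @return Integer distance in nt.
#' @export
mismatchDistance <- function(layout, spacerPosition) {
  stopifnot(is(layout, "DuplexLayout"))
  spacerPosition <- as.integer(spacerPosition)
  bmEnd <- layout@bmStart + layout@bmLength - 1L
  if (spacerPosition < layout@bmStart || spacerPosition > bmEnd) {
    inToehold <- if (layout@toeholdDirection == "5prime")
      spacerPosition >= layout@bmStart - layout@toeholdLengthF &&
        spacerPosition < layout@bmStart
    else
      spacerPosition > bmEnd && spacerPosition <= bmEnd + layout@toeholdLengthF
    if (inToehold) stop("position in toehold")
    stop("spacer position outside the branch-migration domain")
  }
  if (layout@toeholdDirection == "5prime") spacerPosition - layout@bmStart
  else bmEnd - spacerPosition
}

#' Design a toehold-exchange ERA/activator pair
#'
#' Produces an ERA leaving a forward toehold of `fLength` nt at the chosen
#' spacer end, together with an activator truncated at the opposite end so
#' that an `rLength`-nt reverse toehold is exposed after displacement.
#' Feasibility of the reverse toehold is enforced: for the standard 22-nt
#' spacer the activation is predicted to be lost once the terminal deletion
#' reaches 5 nt, so `rLength < 5` is required; extending the spacer to 35 nt
#' relaxes the bound at the spacer 3' end (the activator's own 5' end) to a
#' 19-nt deletion.
#'
#' @param crrna A [CrRNASpec-class].
#' @param direction `"5prime"` or `"3prime"`: end carrying the forward
#'   toehold.
#' @param fLength Forward toehold length, >= 1 nt.
#' @param rLength Reverse toehold length, >= 0 nt (activator deletion at the
#'   end opposite the forward toehold).
#' @return A list with elements `era` ([ERASpec-class]) and `activator`
#'   ([ActivatorSpec-class]).
#' @examples
#' cr22 <- CrRNASpec("ACGUACGUACGUACGUACGUAC")
#' te <- designTeEra(cr22, "3prime", fLength = 9, rLength = 4)
#' buildDuplexLayout(cr22, te$era, te$activator)
#' @export
designTeEra <- function(crrna, direction = c("5prime", "3prime"),
                        fLength, rLength) {
  stopifnot(is(crrna, "CrRNASpec"))
  direction <- match.arg(direction)
  fLength <- as.integer(fLength); rLength <- as.integer(rLength)
  if (fLength < 1L) stop("fLength must be >= 1")
  if (rLength < 0L) stop("rLength must be >= 0")
  L <- spacerLength(crrna)
  ## reverse toehold sits at the end opposite the forward toehold
  rEnd <- if (direction == "5prime") "3prime" else "5prime"
  bound <- if (L >= 35L && rEnd == "3prime") 19L else 4L
  if (rLength > min(bound, L - fLength - 1L))
    stop("reverse toehold infeasible: deletion of ", rLength,
         " nt predicted to abolish activation for a ", L, "-nt spacer")
  era <- designEra(crrna, direction, fLength)
  activator <- if (rEnd == "3prime")
    designActivator(crrna, deletion3p = rLength)
  else designActivator(crrna, deletion5p = rLength)
  list(era = era, activator = activator)
}
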