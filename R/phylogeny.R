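#' Lineage branch lengths for the four-species design
#'
#' Terminal and ancestral branch lengths, in million years (MY), for the
#' human, chimpanzee, macaque-ancestor and mouse-ancestor lineages. The
#' human and chimpanzee terminal branches default to 6.5 MY (the 6-7 MY
#' human-chimpanzee split). The macaque-ancestor branch is the segment from
#' the human-chimpanzee ancestor down to the macaque split, taken as 23 MY
#' (a 29.5 MY macaque split depth minus the 6.5 MY shared with the terminal
#' branches); the mouse-ancestor branch is 101 MY (a 130 MY rodent-primate
#' split minus the 29 MY of primate history it does not traverse). All four
#' are configurable; the regression stage only needs a consistent x-axis.
#'
#' @param human_my,chimp_my,macaque_my,mouse_my branch lengths in MY, all
#'   positive.
#' @return A `phylogeny` object: a named list of the four branch lengths.
#' @examples
#' make_phylogeny()
#' @export
make_phylogeny <- function(human_my = 6.5, chimp_my = 6.5,
                           macaque_my = 23, mouse_my = 101) {
  check_positive_scalar(human_my, "human_my")
  check_positive_scalar(chimp_my, "chimp_my")
  check_positive_scalar(macaque_my, "macaque_my")
  check_positive_scalar(mouse_my, "mouse_my")
  structure(
    list(lineage_lengths = c(
      human = human_my, chimp = chimp_my,
      macaque_anc = macaque_my, mouse_anc = mouse_my
    )),
    class = "phylogeny"
  )
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("<phylogeny> branch lengths (MY):\n")
  print(x$lineage_lengths)
  invisible(x)
}

# Species whose samples carry a shift planted on a given lineage.
lineage_species <- c(
  human = "human", chimp = "chimpanzee",
  macaque_anc = "macaque", mouse_anc = "mouse"
)

# Comparison species for the per-tissue t tests: a primate is contrasted
# with the other primates; the mouse with all primates.
lineage_comparison <- list(
  human = c("chimpanzee", "macaque"),
  chimp = c("human", "macaque"),
  macaque_anc = c("human", "chimpanzee"),
  mouse_anc = c("human", "chimpanzee", "macaque")
)
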