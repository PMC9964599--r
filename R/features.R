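## Pharmacophore feature typing on the annotated heavy-atom graph.
## A deliberately minimal public dictionary:
##   donor      N or O bearing at least one hydrogen
##   acceptor   O (uncharged/anionic) or N with an available lone pair
##              (not quaternary, not a positively charged or pyrrole-type NH)
##   cation     atom with positive formal charge
##   anion      atom with negative formal charge
##   hydrophobe centroid of each connected cluster of aliphatic carbons
##              with no heteroatom neighbour
##   aromatic   centroid of each aromatic ring

.FEATURE_TYPES <- c("donor", "acceptor", "cation", "anion", "hydrophobe",
                    "aromatic")

#' Type pharmacophore features for one conformer
#'
#' @param g molecular graph from [molGraph()].
#' @param xyz heavy-atom coordinates for the conformer.
#' @return data.frame(type, x, y, z); zero rows when no features.
#' @keywords internal
typeFeatures <- function(g, xyz) {
  rows <- list()
  add <- function(type, pt) rows[[length(rows) + 1L]] <<-
    data.frame(type = type, x = pt[1], y = pt[2], z = pt[3])

  deg <- integer(g$nHeavy)
  hetNbr <- logical(g$nHeavy)
  adj <- vector("list", g$nHeavy)
  if (nrow(g$bonds))
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[i]; b <- g$bonds$b[i]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      if (g$elements[b] != "C") hetNbr[a] <- TRUE
      if (g$elements[a] != "C") hetNbr[b] <- TRUE
    }

  for (i in seq_len(g$nHeavy)) {
    el <- g$elements[i]
    if (el %in% c("N", "O")) {
      if (g$hcount[i] >= 1L && g$charge[i] >= 0L)
        add("donor", xyz[i, ])
      lonePair <- if (el == "O") g$charge[i] <= 0L
      else g$charge[i] <= 0L && (deg[i] + g$hcount[i]) < 4L &&
        !(g$aromaticAtoms[i] && g$hcount[i] >= 1L)
      if (lonePair) add("acceptor", xyz[i, ])
    }
    if (g$charge[i] > 0L) add("cation", xyz[i, ])
    if (g$charge[i] < 0L) add("anion", xyz[i, ])
  }

  hydro <- which(g$elements == "C" & !g$aromaticAtoms & !hetNbr &
                   g$charge == 0L)
  if (length(hydro)) {
    seen <- logical(g$nHeavy)
    for (s in hydro) {
      if (seen[s]) next
      comp <- s; queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]])
          if (w %in% hydro && !seen[w]) {
            seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
          }
      }
      add("hydrophobe", colMeans(xyz[comp, , drop = FALSE]))
    }
  }

  for (ring in g$aromaticRings)
    add("aromatic", colMeans(xyz[ring, , drop = FALSE]))

  if (!length(rows))
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
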