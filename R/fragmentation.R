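## Overlapping amide-unit fragmentation with hydrogen capping.
##
## A fragment window of w amide units, offset by one amide, owns every
## residue contributing an atom to any amide unit in the window; side
## chains travel with their residue. Severed backbone bonds are capped with
## hydrogens placed along the severed bond direction at 1.09 A.

#' Enumerate fragment windows over amide units
#'
#' Half-open 0-based index ranges with stride one: a chain with M amide
#' units and window w yields exactly M - w + 1 windows.
#'
#' @param n_amides number of amide units in the chain.
#' @param window number of amide units per fragment (4 or 7 typical).
#' @return integer matrix with columns \code{start}, \code{end} (half-open).
#' @examples
#' enumerate_windows(10, 4)  # 7 windows: (0,4) ... (6,10)
#' @export
enumerate_windows <- function(n_amides, window) {
  if (window < 1 || window > n_amides)
    stop(sprintf("window (%d) must lie in 1..n_amides (%d)", window, n_amides))
  starts <- 0:(n_amides - window)
  cbind(start = starts, end = starts + window)
}

#' Cut one fragment out of a labeled parent geometry
#'
#' Takes the residues spanned by the amide-unit range (the amide between
#' residues r and r+1 pulls in both residues), keeps their atoms, and caps
#' the two severed backbone bonds (C(prev)-N and C-N(next)) with hydrogen
#' atoms at 1.09 \enc{Å}{A} along the severed bond direction.
#'
#' @param parent labeled [geometry()] with amide units.
#' @param chain chain identifier.
#' @param start,end half-open 0-based amide-unit range within the chain.
#' @param capping \code{"hydrogen"} (default) or \code{"none"}.
#' @return object of class \code{fragment}: list with \code{geometry},
#'   \code{atom_map} (data.frame \code{fragment_atom}, \code{parent_atom},
#'   \code{is_cap}), \code{chain}, \code{start}, \code{end}.
#' @export
cut_fragment <- function(parent, chain, start, end,
                         capping = c("hydrogen", "none")) {
  capping <- match.arg(capping)
  if (!length(parent$amide_units))
    stop("parent geometry has no amide-unit labels")
  lb <- parent$labels
  ch_units <- Filter(function(u) u$chain == chain, parent$amide_units)
  ch_amides <- vapply(ch_units, `[[`, 0L, "resno")
  wanted <- start:(end - 1)
  if (!all(wanted %in% ch_amides))
    stop("amide range touches an unlabeled region of chain ", chain)
  residues <- start:end          # amide j joins residues j and j+1
  sel <- which(lb$chain == chain & lb$resno %in% residues)
  sel <- sort(sel)
  el <- parent$elements[sel]
  xyz <- parent$xyz[sel, , drop = FALSE]
  masses <- parent$masses[sel]
  labels <- lb[sel, , drop = FALSE]
  rownames(labels) <- NULL
  map <- data.frame(fragment_atom = seq_along(sel), parent_atom = sel,
                    is_cap = FALSE)
  if (capping == "hydrogen") {
    cap_to <- function(anchor_par, toward_par) {
      dir <- .unit(parent$xyz[toward_par, ] - parent$xyz[anchor_par, ])
      parent$xyz[anchor_par, ] + 1.09 * dir
    }
    add_cap <- function(anchor_par, toward_par) {
      el <<- c(el, "H")
      xyz <<- rbind(xyz, cap_to(anchor_par, toward_par))
      masses <<- c(masses, unname(.monoisotopic["H"]))
      labels <<- rbind(labels, data.frame(
        chain = chain, resno = lb$resno[toward_par], resid = "CAP",
        atom = "HC", stringsAsFactors = FALSE))
      map <<- rbind(map, data.frame(fragment_atom = nrow(map) + 1L,
                                    parent_atom = NA_integer_,
                                    is_cap = TRUE))
    }
    ## N-terminal side: bond C(start-1) -> N(start) severed
    prevC <- which(lb$chain == chain & lb$resno == start - 1 & lb$atom == "C")
    thisN <- which(lb$chain == chain & lb$resno == start & lb$atom == "N")
    if (length(prevC) == 1 && length(thisN) == 1) add_cap(thisN, prevC)
    ## C-terminal side: bond C(end) -> N(end+1) severed
    thisC <- which(lb$chain == chain & lb$resno == end & lb$atom == "C")
    nextN <- which(lb$chain == chain & lb$resno == end + 1 & lb$atom == "N")
    if (length(thisC) == 1 && length(nextN) == 1) add_cap(thisC, nextN)
  }
  frag_geo <- geometry(el, xyz, masses = masses, labels = labels,
                       check = FALSE)
  frag_geo$amide_units <- detect_amide_units(frag_geo)
  structure(list(geometry = frag_geo, atom_map = map, chain = chain,
                 start = start, end = end),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment: chain %s amides [%d,%d), %d atoms (%d caps)\n",
              x$chain, x$start, x$end, n_atoms(x$geometry),
              sum(x$atom_map$is_cap)))
  invisible(x)
}

#' Fragment a whole labeled geometry into overlapping windows
#'
#' Applies [enumerate_windows()] per chain and [cut_fragment()] per window.
#'
#' @param parent labeled [geometry()] with amide units.
#' @param window amide units per fragment (default 4; 7 also standard).
#' @param capping see [cut_fragment()].
#' @return object of class \code{fragment_scheme}: list with \code{window}
#'   and \code{fragments}.
#' @export
fragment_molecule <- function(parent, window = 4,
                              capping = c("hydrogen", "none")) {
  capping <- match.arg(capping)
  if (!length(parent$amide_units))
    stop("parent geometry has no amide-unit labels")
  chains <- unique(vapply(parent$amide_units, `[[`, "", "chain"))
  frags <- list()
  for (ch in chains) {
    m <- sum(vapply(parent$amide_units, `[[`, "", "chain") == ch)
    win <- enumerate_windows(m, window)
    ## amide indices are residue numbers of the carbonyl donor
    first <- min(vapply(Filter(function(u) u$chain == ch,
                               parent$amide_units), `[[`, 0L, "resno"))
    for (k in seq_len(nrow(win)))
      frags[[length(frags) + 1L]] <-
        cut_fragment(parent, ch, first + win[k, "start"],
                     first + win[k, "end"], capping)
  }
  structure(list(window = as.integer(window), fragments = frags),
            class = "fragment_scheme")
}

#' @export
print.fragment_scheme <- function(x, ...) {
  cat(sprintf("fragment_scheme: window %d, %d fragments\n",
              x$window, length(x$fragments)))
  invisible(x)
}

#' Write a fragment scheme to a directory of XYZ files plus a JSON manifest
#'
#' @param scheme a [fragment_molecule()] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_fragments <- function(scheme, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(scheme$fragments), function(k) {
    fr <- scheme$fragments[[k]]
    fn <- sprintf("frag_%03d.xyz", k)
    write_xyz(fr$geometry, file.path(dir, fn),
              comment = sprintf("chain %s amides [%d,%d)",
                                fr$chain, fr$start, fr$end))
    list(file = fn, chain = fr$chain, start = fr$start, end = fr$end,
         parent_atom = fr$atom_map$parent_atom,
         is_cap = fr$atom_map$is_cap)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(window = scheme$window, fragments = entries),
    manifest, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(manifest)
}

#' Read a fragment scheme back from a directory
#'
#' @param dir directory written by [write_fragments()].
#' @return a \code{fragment_scheme}; fragment geometries carry no residue
#'   labels beyond what XYZ preserves.
#' @export
read_fragments <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  frags <- lapply(seq_len(nrow(manifest$fragments)), function(k) {
    e <- manifest$fragments[k, ]
    geo <- read_xyz(file.path(dir, e$file))
    map <- data.frame(fragment_atom = seq_along(e$is_cap[[1]]),
                      parent_atom = unlist(e$parent_atom),
                      is_cap = unlist(e$is_cap))
    structure(list(geometry = geo, atom_map = map, chain = e$chain,
                   start = e$start, end = e$end), class = "fragment")
  })
  structure(list(window = as.integer(manifest$window), fragments = frags),
            class = "fragment_scheme")
}
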