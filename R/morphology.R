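#' Branched dendritic morphology
#'
#' A `neurite_tree` holds the sections of a motoneuron morphology: a single
#' soma section (the root), dendritic sections forming an acyclic tree, and
#' the fixed axonal hillock + initial-segment geometry (a 20 um cable
#' tapering 13 -> 3.3 um followed by a 30 um cable of constant 3.3 um
#' diameter). Lengths and diameters are in micrometres internally; path
#' lengths are exposed in millimetres at the API surface.
#'
#' @param sections A data frame with columns `id` (integer), `parent`
#'   (integer, `NA` for the root), `kind` (one of `"soma"`, `"dendrite"`,
#'   `"hillock"`, `"initial_segment"`), `length` (um), `diam_prox` and
#'   `diam_dist` (um). Rows must be in topological order (parents before
#'   children).
#' @return An object of class `neurite_tree`.
#' @export
neurite_tree <- function(sections) {
  sections <- tibble::as_tibble(sections)
  need <- c("id", "parent", "kind", "length", "diam_prox", "diam_dist")
  missing <- setdiff(need, names(sections))
  if (length(missing) > 0) {
    stop("sections is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  roots <- which(is.na(sections$parent))
  if (length(roots) != 1) {
    stop("tree must have exactly one root section (found ", length(roots), ")",
         call. = FALSE)
  }
  if (sections$kind[roots] != "soma") {
    stop("root section must be the soma", call. = FALSE)
  }
  if (sum(sections$kind == "soma") != 1) {
    stop("tree must contain exactly one soma section", call. = FALSE)
  }
  if (anyDuplicated(sections$id)) {
    stop("section ids must be unique", call. = FALSE)
  }
  if (any(sections$length <= 0)) stop("section lengths must be > 0", call. = FALSE)
  if (any(sections$diam_prox <= 0) || any(sections$diam_dist <= 0)) {
    stop("section diameters must be > 0", call. = FALSE)
  }
  # parents must exist and precede their children (acyclicity by construction)
  pos <- match(sections$parent, sections$id)
  bad <- which(!is.na(sections$parent) & is.na(pos))
  if (length(bad) > 0) {
    stop("section ", sections$id[bad[1]], " references undefined parent ",
         sections$parent[bad[1]], call. = FALSE)
  }
  if (any(pos[!is.na(pos)] >= seq_len(nrow(sections))[!is.na(pos)])) {
    stop("sections must be topologically ordered (parents before children)",
         call. = FALSE)
  }
  structure(
    list(sections = sections, root = sections$id[roots]),
    class = "neurite_tree"
  )
}

#' @export
print.neurite_tree <- function(x, ...) {
  s <- x$sections
  nd <- sum(s$kind == "dendrite")
  cat("<neurite_tree> ", nrow(s), " sections (", nd, " dendritic), ",
      sum(s$parent %in% x$root & s$kind == "dendrite"), " stems\n", sep = "")
  cat("  max dendritic path: ", round(max_dendritic_path(x), 3), " mm; ",
      "membrane area: ", round(tree_area(x)), " um^2\n", sep = "")
  invisible(x)
}

# lateral (frustum) membrane area of one section, um^2
section_area <- function(length, diam_prox, diam_dist) {
  pi * (diam_prox + diam_dist) / 2 * length
}

#' Total membrane area of a tree (um^2)
#' @param tree A [neurite_tree()].
#' @param kinds Section kinds to include (default: all).
#' @export
tree_area <- function(tree, kinds = unique(tree$sections$kind)) {
  s <- tree$sections[tree$sections$kind %in% kinds, ]
  sum(section_area(s$length, s$diam_prox, s$diam_dist))
}

# Path length (um) from the soma centre to the proximal end of each section.
# The soma is the path origin: sections attached to the soma start at 0.
section_path_start <- function(tree) {
  s <- tree$sections
  start <- numeric(nrow(s))
  idx <- match(s$parent, s$id)
  for (i in seq_len(nrow(s))) {
    if (is.na(idx[i])) {
      start[i] <- 0
    } else if (s$kind[idx[i]] == "soma") {
      start[i] <- 0
    } else {
      start[i] <- start[idx[i]] + s$length[idx[i]]
    }
  }
  start
}

#' Path length from the soma to a point on a section
#'
#' @param tree A [neurite_tree()].
#' @param section Section id.
#' @param arc Normalized position along the section in `[0, 1]`.
#' @return Path length in mm.
#' @export
path_length_to <- function(tree, section, arc = 1) {
  i <- match(section, tree$sections$id)
  if (is.na(i)) stop("section ", section, " not in tree", call. = FALSE)
  stopifnot(arc >= 0, arc <= 1)
  (section_path_start(tree)[i] + arc * tree$sections$length[i]) / 1000
}

#' Maximal dendritic path length (mm)
#' @param tree A [neurite_tree()].
#' @export
max_dendritic_path <- function(tree) {
  s <- tree$sections
  start <- section_path_start(tree)
  dend <- s$kind == "dendrite"
  if (!any(dend)) return(0)
  max(start[dend] + s$length[dend]) / 1000
}

# Standard hillock + initial-segment sections appended to every morphology.
hillock_sections <- function(next_id, soma_id) {
  tibble::tibble(
    id = c(next_id, next_id + 1L),
    parent = c(soma_id, next_id),
    kind = c("hillock", "initial_segment"),
    length = c(20, 30),
    diam_prox = c(13, 3.3),
    diam_dist = c(3.3, 3.3)
  )
}

#' Read a neuron morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments, 1-based ids). Soma samples (type 1) are collapsed to a
#' single equivalent-area cylindrical section with length equal to its
#' diameter; dendritic samples (types 3 and 4) become tapered cable
#' sections, one per SWC sample, with length equal to the Euclidean
#' distance to the parent sample. Axonal samples (type 2) are discarded;
#' the standard hillock + initial-segment geometry is appended instead.
#'
#' @param path Path to an SWC file.
#' @return A [neurite_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("SWC file contains no data rows", call. = FALSE)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  n_ok <- vapply(fields, length, 1L) == 7L
  if (!all(n_ok)) {
    stop("malformed SWC row at line ", rows[which(!n_ok)[1]],
         ": expected 7 fields", call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- rows[which(rowSums(is.na(m)) > 0)[1]]
    stop("malformed SWC row at line ", bad, ": non-numeric field", call. = FALSE)
  }
  swc <- tibble::tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6],
    parent = as.integer(m[, 7])
  )
  if (anyDuplicated(swc$id)) stop("duplicate SWC sample ids", call. = FALSE)
  undef <- swc$parent != -1 & !(swc$parent %in% swc$id)
  if (any(undef)) {
    stop("SWC sample ", swc$id[which(undef)[1]], " has undefined parent ",
         swc$parent[which(undef)[1]], call. = FALSE)
  }

  soma_rows <- swc[swc$type == 1, ]
  if (nrow(soma_rows) == 0) stop("SWC file has no soma sample", call. = FALSE)
  # a single connected soma cluster is required
  soma_ids <- soma_rows$id
  soma_roots <- soma_rows$id[!(soma_rows$parent %in% soma_ids)]
  if (length(soma_roots) > 1) {
    stop("multiple somas: ", length(soma_roots),
         " disconnected soma clusters found", call. = FALSE)
  }
  # equivalent-area soma cylinder (L = D); single sample -> sphere area 4*pi*r^2
  if (nrow(soma_rows) == 1) {
    soma_area <- 4 * pi * soma_rows$r[1]^2
  } else {
    pidx <- match(soma_rows$parent, swc$id)
    seg <- soma_rows[soma_rows$parent %in% soma_ids, ]
    pj <- match(seg$parent, swc$id)
    len <- sqrt((seg$x - swc$x[pj])^2 + (seg$y - swc$y[pj])^2 +
                  (seg$z - swc$z[pj])^2)
    soma_area <- sum(pi * (seg$r + swc$r[pj]) * pmax(len, 1e-9))
  }
  soma_diam <- sqrt(soma_area / pi)

  # dendritic sections: one per non-soma sample of type 3/4
  dend <- swc[swc$type %in% c(3L, 4L), ]
  ord <- order(dend$id)  # SWC guarantees parent id < child id in practice;
  dend <- dend[ord, ]    # sort defensively and then verify topological order
  pidx <- match(dend$parent, swc$id)
  plen <- sqrt((dend$x - swc$x[pidx])^2 + (dend$y - swc$y[pidx])^2 +
                 (dend$z - swc$z[pidx])^2)
  if (any(plen <= 0)) {
    stop("SWC sample ", dend$id[which(plen <= 0)[1]],
         " coincides with its parent", call. = FALSE)
  }
  soma_sec_id <- 1L
  id_map <- stats::setNames(seq_len(nrow(dend)) + 1L, dend$id)
  parent_sec <- ifelse(swc$type[pidx] == 1L, soma_sec_id,
                       unname(id_map[as.character(dend$parent)]))
  if (anyNA(parent_sec)) {
    stop("dendritic SWC sample attached to a non-dendritic, non-soma parent",
         call. = FALSE)
  }
  sections <- tibble::tibble(
    id = c(soma_sec_id, unname(id_map)),
    parent = c(NA_integer_, as.integer(parent_sec)),
    kind = c("soma", rep("dendrite", nrow(dend))),
    length = c(soma_diam, plen),
    diam_prox = c(soma_diam, 2 * swc$r[pidx]),
    diam_dist = c(soma_diam, 2 * dend$r)
  )
  sections <- sections[order(match(sections$parent, sections$id),
                             na.last = FALSE), ]
  next_id <- max(sections$id) + 1L
  sections <- dplyr::bind_rows(sections, hillock_sections(next_id, soma_sec_id))
  neurite_tree(sections)
}

#' Write a morphology to an SWC file
#'
#' The soma is written as a single type-1 sample of equivalent area; each
#' dendritic section becomes one type-3 sample at its distal end, placed at
#' the correct Euclidean (= path) distance from its parent sample so that
#' `read_swc()` round-trips topology and section lengths. The hillock and
#' initial segment are not written: `read_swc()` re-appends the standard
#' geometry.
#'
#' @param tree A [neurite_tree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  s <- tree$sections
  soma <- s[s$kind == "soma", ]
  dend <- s[s$kind == "dendrite", ]
  soma_r <- sqrt(section_area(soma$length, soma$diam_prox, soma$diam_dist) / (4 * pi))
  ids <- c(soma$id, dend$id)
  swc_id <- stats::setNames(seq_along(ids), ids)
  # deterministic directions: spread children of one parent over distinct
  # unit vectors so samples never coincide
  xyz <- matrix(0, nrow = length(ids), ncol = 3)
  out_parent <- integer(length(ids))
  out_parent[1] <- -1L
  for (i in seq_len(nrow(dend))) {
    row <- i + 1L
    p <- dend$parent[i]
    prow <- swc_id[as.character(p)]
    k <- sum(dend$parent[seq_len(i)] == p)  # child index under this parent
    theta <- 2.39996 * (swc_id[as.character(dend$id[i])] + k)  # golden angle
    u <- c(cos(theta), sin(theta), 0.3 * sin(0.5 * theta))
    u <- u / sqrt(sum(u^2))
    xyz[row, ] <- xyz[prow, ] + dend$length[i] * u
    out_parent[row] <- as.integer(swc_id[as.character(p)])
  }
  radius <- c(soma_r, dend$diam_dist / 2)
  type <- c(1L, rep(3L, nrow(dend)))
  lines <- c(
    "# SWC written by motorunit (soma as single equivalent-area sample)",
    sprintf("%d %d %.9f %.9f %.9f %.9f %d",
            seq_along(ids), type, xyz[, 1], xyz[, 2], xyz[, 3],
            radius, out_parent)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic adult-cat-scale motoneuron morphology
#'
#' Builds a parametric dendritic arbor emulating the scale of an adult cat
#' alpha-motoneuron: `n_stems` stem dendrites leave the soma, each reaching a
#' root-to-tip path length of exactly `max_path_mm` through `branch_depth`
#' symmetric binary branch points, with diameters tapering linearly with
#' path length and stepping down at branch points by the Rall 3/2 rule
#' (`d_parent^1.5 = sum d_child^1.5`). Randomness (per-stem diameter jitter
#' and branch-position jitter) is controlled by `seed` and does not affect
#' tip path lengths, so every path-length band up to `max_path_mm` is
#' populated on every stem.
#'
#' @param n_stems Number of stem dendrites (default 10).
#' @param max_path_mm Root-to-tip path length of every stem, mm (default 1.8).
#' @param stem_diam_um Nominal stem diameter, um (default 9).
#' @param taper_per_mm Fractional diameter reduction per mm of path
#'   (default 0.25).
#' @param branch_depth Number of binary branch orders (default 3).
#' @param soma_diam_um Soma diameter = length, um (default 48.8).
#' @param min_diam_um Diameter floor, um (default 0.8). A floor of 0 with
#'   parameters that taper through zero raises an error.
#' @param seed Integer seed; the same seed yields an identical tree.
#' @return A [neurite_tree()] with attribute `arbor_area_um2` reporting the
#'   dendritic membrane area.
#' @export
synthetic_motoneuron <- function(n_stems = 10, max_path_mm = 1.8,
                                 stem_diam_um = 9, taper_per_mm = 0.25,
                                 branch_depth = 3, soma_diam_um = 48.8,
                                 min_diam_um = 0.8, seed = 1) {
  stopifnot(n_stems >= 1, max_path_mm > 0, branch_depth >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  total_um <- max_path_mm * 1000
  secs <- list(tibble::tibble(
    id = 1L, parent = NA_integer_, kind = "soma",
    length = soma_diam_um, diam_prox = soma_diam_um, diam_dist = soma_diam_um
  ))
  next_id <- 2L

  taper_diam <- function(d_prox, start_um, len_um) {
    d <- d_prox * (1 - taper_per_mm * len_um / 1000)
    if (d <= 0 && min_diam_um <= 0) {
      stop("taper parameters yield a zero-diameter segment at path ",
           round((start_um + len_um) / 1000, 3), " mm", call. = FALSE)
    }
    max(d, min_diam_um)
  }

  for (s in seq_len(n_stems)) {
    # per-level path budget: trunk takes ~35%, remaining levels share the
    # rest; jitter the split (not the total) so tips stay at max_path
    n_lev <- branch_depth + 1
    if (n_lev == 1) {
      fracs <- 1
    } else {
      w <- c(0.35, rep(0.65 / branch_depth, branch_depth)) *
        stats::runif(n_lev, 0.85, 1.15)
      fracs <- w / sum(w)
    }
    lens <- fracs * total_um
    d0 <- stem_diam_um * stats::runif(1, 0.9, 1.1)

    grow <- function(parent_id, level, start_um, d_prox) {
      len <- lens[level]
      d_dist <- taper_diam(d_prox, start_um, len)
      sec <- tibble::tibble(
        id = next_id, parent = parent_id, kind = "dendrite",
        length = len, diam_prox = d_prox, diam_dist = d_dist
      )
      next_id <<- next_id + 1L
      secs[[length(secs) + 1L]] <<- sec
      if (level < n_lev) {
        d_child <- max(d_dist * 2^(-2 / 3), min_diam_um)
        grow(sec$id, level + 1L, start_um + len, d_child)
        grow(sec$id, level + 1L, start_um + len, d_child)
      }
    }
    grow(1L, 1L, 0, d0)
  }

  sections <- dplyr::bind_rows(secs)
  sections <- dplyr::bind_rows(sections, hillock_sections(next_id, 1L))
  tree <- neurite_tree(sections)
  attr(tree, "arbor_area_um2") <- tree_area(tree, kinds = "dendrite")
  tree
}

#' Passive membrane parameters
#'
#' Specific membrane resistivity is nonuniform: low at the soma (a somatic
#' shunt) and rising sigmoidally with dendritic path length to a distal
#' plateau, as used for cat motoneuron models. Capacitance and axial
#' resistivity are uniform.
#'
#' @param rm_soma_kohm_cm2 Somatic specific membrane resistivity
#'   (kOhm cm^2, default 0.1).
#' @param rm_dend_kohm_cm2 Distal dendritic plateau (default 25).
#' @param rm_half_mm Path length at the sigmoid midpoint (default 0.1 mm).
#' @param rm_slope_mm Sigmoid slope (default 0.05 mm).
#' @param ri_ohm_cm Axial resistivity (default 70).
#' @param cm_uf_cm2 Specific capacitance (default 1).
#' @param e_leak_mv Leak reversal potential (default -70).
#' @return A list of class `passive_params`.
#' @export
passive_params <- function(rm_soma_kohm_cm2 = 0.1, rm_dend_kohm_cm2 = 25,
                           rm_half_mm = 0.1, rm_slope_mm = 0.05,
                           ri_ohm_cm = 70, cm_uf_cm2 = 1, e_leak_mv = -70) {
  structure(list(
    rm_soma_kohm_cm2 = rm_soma_kohm_cm2,
    rm_dend_kohm_cm2 = rm_dend_kohm_cm2,
    rm_half_mm = rm_half_mm, rm_slope_mm = rm_slope_mm,
    ri_ohm_cm = ri_ohm_cm, cm_uf_cm2 = cm_uf_cm2, e_leak_mv = e_leak_mv
  ), class = "passive_params")
}

# R_m (kOhm cm^2) at a dendritic path length (mm); the soma and the
# hillock/initial segment use the somatic value
rm_at_path <- function(passive, path_mm, kind = "dendrite") {
  rm <- passive$rm_soma_kohm_cm2 +
    (passive$rm_dend_kohm_cm2 - passive$rm_soma_kohm_cm2) /
    (1 + exp((passive$rm_half_mm - path_mm) / passive$rm_slope_mm))
  somatic <- rep_len(kind %in% c("soma", "hillock", "initial_segment"),
                     length(rm))
  rm[somatic] <- passive$rm_soma_kohm_cm2
  rm
}

# local space constant lambda (mm) for diameter d (um) at path p (mm)
lambda_at <- function(passive, d_um, path_mm, kind = "dendrite") {
  rm <- rm_at_path(passive, path_mm, kind) * 1000   # Ohm cm^2
  d_cm <- d_um * 1e-4
  sqrt(rm * d_cm / (4 * passive$ri_ohm_cm)) * 10    # cm -> mm
}

# diameter (um) at arc position within a section (linear taper)
diam_at_arc <- function(sec, arc) sec$diam_prox + arc * (sec$diam_dist - sec$diam_prox)

# ancestor chain of section ids from a soma child down to `section`
section_chain <- function(tree, section) {
  s <- tree$sections
  chain <- integer(0)
  cur <- match(section, s$id)
  if (is.na(cur)) stop("section ", section, " not in tree", call. = FALSE)
  while (!is.na(cur) && s$kind[cur] != "soma") {
    chain <- c(s$id[cur], chain)
    cur <- match(s$parent[cur], s$id)
  }
  chain
}

#' Electrotonic path length from the soma to a dendritic site
#'
#' Integrates `dx / lambda(x)` along the soma-to-site path, with the local
#' space constant `lambda(x) = sqrt(R_m(x) d(x) / (4 R_i))` evaluated from
#' the local diameter and the (possibly nonuniform) membrane resistivity.
#'
#' @param tree A [neurite_tree()].
#' @param section Section id of the site.
#' @param arc Normalized arc position of the site in `[0, 1]`.
#' @param passive A [passive_params()] set.
#' @param step_um Integration step (um, default 1).
#' @return Dimensionless electrotonic distance (units of lambda).
#' @export
electrotonic_path <- function(tree, section, arc = 0.5,
                              passive = passive_params(), step_um = 1) {
  s <- tree$sections
  start <- section_path_start(tree)
  chain <- section_chain(tree, section)
  total <- 0
  for (sid in chain) {
    i <- match(sid, s$id)
    sec <- s[i, ]
    end_arc <- if (sid == section) arc else 1
    len <- sec$length * end_arc
    if (len <= 0) next
    n <- max(2L, ceiling(len / step_um) + 1L)
    x <- seq(0, len, length.out = n)
    arcx <- x / sec$length
    d <- diam_at_arc(sec, arcx)
    p_mm <- (start[i] + x) / 1000
    invl <- 1 / lambda_at(passive, d, p_mm, sec$kind)
    total <- total + sum((invl[-1] + invl[-n]) / 2 * diff(x)) / 1000
  }
  total
}

#' Select a dendritic path-length band for channel or synapse placement
#'
#' Returns one site per discretized dendritic segment whose midpoint path
#' length falls within `[center - halfwidth, center + halfwidth]` mm, on all
#' branches, mirroring the hot-spot placement of PIC channels at a common
#' path length from the soma.
#'
#' @param tree A [neurite_tree()].
#' @param center_mm Band centre (mm path length from the soma).
#' @param halfwidth_mm Band half-width (mm, default 0.1).
#' @param passive A [passive_params()] set used for electrotonic lengths.
#' @param step_um Segment length used to discretize sections (um, default 20).
#' @return A tibble (`site_set`) with columns `section`, `arc`, `path_mm`,
#'   `area_um2`, `lambda_dist`, and attributes `center_mm`, `halfwidth_mm`.
#' @export
select_band <- function(tree, center_mm, halfwidth_mm = 0.1,
                        passive = passive_params(), step_um = 20) {
  s <- tree$sections
  start <- section_path_start(tree)
  lo <- center_mm - halfwidth_mm
  hi <- center_mm + halfwidth_mm
  rows <- list()
  for (i in seq_len(nrow(s))) {
    if (s$kind[i] != "dendrite") next
    n <- max(1L, ceiling(s$length[i] / step_um))
    edges <- seq(0, s$length[i], length.out = n + 1)
    mid <- (edges[-1] + edges[-(n + 1)]) / 2
    p_mm <- (start[i] + mid) / 1000
    inb <- p_mm >= lo & p_mm <= hi
    if (!any(inb)) next
    arc <- mid[inb] / s$length[i]
    seg_len <- diff(edges)[inb]
    d <- diam_at_arc(s[i, ], arc)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      section = s$id[i], arc = arc, path_mm = p_mm[inb],
      area_um2 = pi * d * seg_len
    )
  }
  if (length(rows) == 0) {
    stop("empty band: no dendritic segment midpoint lies in [",
         lo, ", ", hi, "] mm", call. = FALSE)
  }
  sites <- dplyr::bind_rows(rows)
  sites$lambda_dist <- purrr::map2_dbl(
    sites$section, sites$arc,
    function(sec, a) electrotonic_path(tree, sec, a, passive, step_um = 5)
  )
  attr(sites, "center_mm") <- center_mm
  attr(sites, "halfwidth_mm") <- halfwidth_mm
  class(sites) <- c("site_set", class(sites))
  sites
}
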