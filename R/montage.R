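#' Standard 64-channel 10-10 montage with neighbor graph
#'
#' Builds a schematic flattened 2-D layout of a 64-channel 10-10 cap (the
#' common actiCHamp roster, nose reference, plus the intermediate
#' parieto-occipital sites `PO1`/`PO2` placed midway between `PO3`/`PO4` and
#' `POz`). Positions are laid on a regular anterior-posterior by lateral grid
#' (arbitrary units, spacing 0.9); they are used only for neighbor finding and
#' inverse-distance channel repair, not for source modelling.
#'
#' @param neighbor_radius Channels closer than this (grid units) are montage
#'   neighbors. The default 1.4 connects each interior channel to its
#'   horizontal, vertical and diagonal grid neighbors.
#' @return An object of class `montage`: a list with `positions` (tibble of
#'   `channel`, `x`, `y`) and `neighbors` (named list of character vectors).
#' @examples
#' m <- montage_1010()
#' m$neighbors[["Fz"]]
#' @export
montage_1010 <- function(neighbor_radius = 1.4) {
  sp <- 0.9
  row_y <- c(Fp = 4, AF = 3, F = 2, FC = 1, C = 0, CP = -1, P = -2, PO = -3, O = -4)
  # column index -> lateral position (odd numbers left/negative, even right)
  colx <- function(lab) {
    n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", lab)))
    if (is.na(n)) return(0) # z line
    side <- if (n %% 2 == 1) -1 else 1
    side * ceiling(n / 2)
  }
  rows <- list(
    Fp = c("Fp1", "Fpz", "Fp2"),
    AF = c("AF7", "AF3", "AF4", "AF8"),
    F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    FC = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    C  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    CP = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    P  = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
    O  = c("O1", "Oz", "O2")
  )
  pos <- do.call(rbind, lapply(names(rows), function(rn) {
    chans <- rows[[rn]]
    data.frame(
      channel = chans,
      x = vapply(chans, function(ch) {
        cx <- colx(ch)
        # lateral temporal rows reuse the 7/8 index for T7/T8, FT7 etc.
        if (grepl("^(T|TP|FT)[78]$", ch)) cx <- sign(cx) * 4
        cx * sp
      }, numeric(1)),
      y = row_y[[rn]] * sp,
      stringsAsFactors = FALSE
    )
  }))
  # PO1/PO2 sit midway between PO3/PO4 and POz; PO9/PO10 below PO7/PO8
  extra <- data.frame(
    channel = c("PO1", "PO2", "PO9", "PO10"),
    x = c(-0.9, 0.9, -3.4, 3.4),
    y = c(-3 * sp, -3 * sp, -3.5 * sp, -3.5 * sp),
    stringsAsFactors = FALSE
  )
  pos <- rbind(pos, extra)
  rownames(pos) <- NULL
  m <- structure(
    list(positions = tibble::as_tibble(pos), neighbors = NULL,
         radius = neighbor_radius),
    class = "montage"
  )
  m$neighbors <- compute_neighbors(m$positions, neighbor_radius)
  m
}

compute_neighbors <- function(pos, radius) {
  d <- as.matrix(stats::dist(pos[, c("x", "y")]))
  nb <- lapply(seq_len(nrow(pos)), function(i) {
    pos$channel[which(d[i, ] > 0 & d[i, ] <= radius)]
  })
  names(nb) <- pos$channel
  nb
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", nrow(x$positions), " channels, neighbor radius ",
      x$radius, "\n", sep = "")
  invisible(x)
}

#' Electrode-of-interest scheme for frontoparietal connectivity
#'
#' The three clusters used for long-range phase-coupling analyses: a
#' fronto-medial cluster and two symmetric parietal clusters.
#'
#' @param fm,pl,pr Channel name vectors for the fronto-medial, parietal-left
#'   and parietal-right clusters.
#' @return A list of class `eoi_scheme`.
#' @examples
#' eoi_scheme()
#' @export
eoi_scheme <- function(fm = c("Fz", "FC1", "FC2"),
                       pl = c("P3", "PO3", "PO1"),
                       pr = c("P4", "PO4", "PO2")) {
  if (anyDuplicated(c(fm, pl, pr))) {
    abort("EOI clusters must be disjoint.", class = "alphasync_bad_scheme")
  }
  structure(list(fm = fm, pl = pl, pr = pr), class = "eoi_scheme")
}

#' Electrode sets for parieto-occipital power lateralization
#'
#' @param pl,pr Left and right parieto-occipital channel sets over which
#'   alpha power is averaged before the lateralization index.
#' @return A list of class `power_eois`.
#' @export
power_eois <- function(pl = c("P5", "P7", "PO3", "O1"),
                       pr = c("P6", "P8", "PO4", "O2")) {
  if (anyDuplicated(c(pl, pr))) {
    abort("Power EOI sets must be disjoint.", class = "alphasync_bad_scheme")
  }
  structure(list(pl = pl, pr = pr), class = "power_eois")
}

#' Parieto-occipital channels used for resting-state IAF estimation
#' @return Character vector of channel names.
#' @export
iaf_channels <- function() {
  c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO3", "PO4", "POz", "PO9", "PO10", "O1", "Oz", "O2")
}

check_channels <- function(wanted, available, what = "channel") {
  missing <- setdiff(wanted, available)
  if (length(missing) > 0) {
    abort(paste0("Unknown ", what, "(s): ", paste(missing, collapse = ", ")),
          class = "alphasync_unknown_channel")
  }
  invisible(TRUE)
}
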