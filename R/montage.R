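#' Idealised 10-20 / 10-10 electrode montage
#'
#' Builds a spherical-head montage with standard extended 10-20 labels.
#' Positions are idealised: electrodes sit on a unit sphere, parameterised by
#' inclination from the vertex and azimuth from the front midline (negative =
#' left). The geometry is accurate enough for spherical-spline interpolation,
#' topography-based channel scoring and declaring channel sets; it makes no
#' claim of matching any digitised cap.
#'
#' Channels are ordered by priority so that `montage_1020(n)` with small `n`
#' still contains the vertex channel (Cz), a neck row (TP9/TP10-like), a
#' lateral temporal pair and midline channels, as the synthetic generator and
#' the footprint features require.
#'
#' @param n_channels number of channels to return (2..63; the 64th entry is
#'   the FCz reference, reconstructed by [rereference_car()], and is not
#'   part of a recorded montage).
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere; +y =
#'   nose, +x = right, +z = vertex), `inc` and `azi` (degrees).
#' @examples
#' mont <- montage_1020(16)
#' channel_sets(mont)$neck
#' @export
montage_1020 <- function(n_channels = 63) {
  tab <- montage_table()
  tab <- tab[tab$label != "FCz", ]
  if (n_channels < 2 || n_channels > nrow(tab)) {
    stop("n_channels must be between 2 and ", nrow(tab))
  }
  tab[seq_len(n_channels), , drop = FALSE]
}

# Full priority-ordered montage table; built in code, not shipped as data.
montage_table <- function() {
  e <- function(label, inc, azi) data.frame(label = label, inc = inc, azi = azi)
  rows <- rbind(
    # high-priority core: vertex, temporal rim, neck row, midline, frontal
    e("Cz", 0, 0),     e("T7", 90, -90),  e("T8", 90, 90),
    e("TP9", 112.5, -108), e("TP10", 112.5, 108),
    e("Fz", 45, 0),    e("Pz", 45, 180),  e("Fpz", 90, 0), e("Oz", 90, 180),
    e("C3", 45, -90),  e("C4", 45, 90),   e("F3", 45, -45), e("F4", 45, 45),
    e("P3", 45, -135), e("P4", 45, 135),  e("Fp1", 90, -18), e("Fp2", 90, 18),
    # posterior/temporal coverage so reduced montages keep the rim and
    # lowest rows spatially predictable
    e("POz", 67.5, 180), e("O1", 90, -162), e("O2", 90, 162),
    e("P7", 90, -126), e("P8", 90, 126), e("F7", 90, -54), e("F8", 90, 54),
    e("FC1", 22.5, -45), e("FC2", 22.5, 45), e("C1", 22.5, -90),
    e("C2", 22.5, 90),   e("CP1", 22.5, -135), e("CP2", 22.5, 135),
    e("CPz", 22.5, 180), e("AFz", 67.5, 0),
    # remaining extended 10-10 rings
    e("FC3", 45, -65),  e("FC4", 45, 65), e("CP3", 45, -115), e("CP4", 45, 115),
    e("AF3", 67.5, -30), e("AF4", 67.5, 30),
    e("F5", 67.5, -55), e("F6", 67.5, 55), e("FC5", 67.5, -75),
    e("FC6", 67.5, 75), e("C5", 67.5, -90), e("C6", 67.5, 90),
    e("CP5", 67.5, -105), e("CP6", 67.5, 105), e("P5", 67.5, -125),
    e("P6", 67.5, 125), e("PO3", 67.5, -150), e("PO4", 67.5, 150),
    e("AF7", 90, -36), e("AF8", 90, 36),
    e("FT7", 90, -72), e("FT8", 90, 72), e("TP7", 90, -108),
    e("TP8", 90, 108),
    e("PO7", 90, -144), e("PO8", 90, 144),
    # below-equator neck ring
    e("P9", 112.5, -126), e("P10", 112.5, 126),
    e("O9", 112.5, -162), e("O10", 112.5, 162), e("Iz", 112.5, 180),
    # online reference; last so montage_1020(n < 64) never includes it and
    # rereference_car() can reconstruct it
    e("FCz", 22.5, 0)
  )
  inc <- rows$inc * pi / 180
  azi <- rows$azi * pi / 180
  rows$x <- sin(inc) * sin(azi)
  rows$y <- sin(inc) * cos(azi)
  rows$z <- cos(inc)
  rows[, c("label", "x", "y", "z", "inc", "azi")]
}

#' Declare the channel sets used by artifact scoring and the footprint
#'
#' Sets are derived from montage geometry rather than hard-coded labels so
#' they remain valid for reduced montages:
#' \describe{
#'   \item{vertex}{the channel closest to the vertex (Cz in full montages).}
#'   \item{neck}{the lowest electrode row (inclination > 100 degrees), the
#'     typical seat of neck-muscle EMG.}
#'   \item{lateral}{temporal/parietal rim: inclination >= 85 degrees,
#'     excluding neck and midline channels.}
#'   \item{medial}{midline +/- one column (|x| < 0.25), above the neck row.}
#'   \item{frontal}{anterior channels (y > 0.55), used for eye-component
#'     scoring.}
#' }
#'
#' @param montage data.frame from [montage_1020()].
#' @return named list of character vectors of channel labels.
#' @export
channel_sets <- function(montage) {
  lab <- montage$label
  neck <- lab[montage$inc > 100]
  lateral <- setdiff(lab[montage$inc >= 85 & abs(montage$x) > 0.5], neck)
  medial <- setdiff(lab[abs(montage$x) < 0.25 & montage$inc <= 100], neck)
  frontal <- lab[montage$y > 0.55]
  vertex <- lab[which.max(montage$z)]
  list(vertex = vertex, neck = neck, lateral = lateral,
       medial = medial, frontal = frontal)
}
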