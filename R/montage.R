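#' Electrode montage
#'
#' A montage is the ordered list of electrode labels attached to a recording,
#' with a coarse cortical region for each channel. Regions drive the
#' representative-channel selection in [select_representative_channels()]:
#' the frontal and parietal cortices are the areas reported to carry
#' planning/execution information for reaching movements.
#'
#' @param names Character vector of unique electrode labels (10/20 system).
#' @param region Character vector, one of `"frontal"`, `"parietal"`,
#'   `"other"` per channel.
#' @return An object of class `pk_montage`: a data frame with columns
#'   `channel` and `region`.
#' @seealso [default_montage()]
#' @export
montage <- function(names, region) {
  if (anyDuplicated(names)) {
    pk_stop("montage channel names must be unique (duplicated: %s)",
            paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (length(names) != length(region)) {
    pk_stop("montage needs one region per channel (%d names, %d regions)",
            length(names), length(region))
  }
  region <- match.arg(region, c("frontal", "parietal", "other"), several.ok = TRUE)
  out <- data.frame(channel = as.character(names), region = region,
                    stringsAsFactors = FALSE)
  class(out) <- c("pk_montage", "data.frame")
  out
}

#' Default 33-channel fronto-central-parietal montage
#'
#' A 33-channel subset of the 10/20 64-channel layout covering the frontal
#' (F, FC rows), central (C row) and parietal (CP, P rows) cortices, midline
#' plus lateral sites. Channel identity does not affect any algorithm in the
#' package, only labelling and the frontal/parietal region split used for
#' representative-channel selection; supply your own [montage()] to override.
#'
#' @return A `pk_montage` with 33 channels.
#' @export
default_montage <- function() {
  rows <- list(
    F  = c("F3", "F1", "Fz", "F2", "F4"),
    FC = c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6"),
    C  = c("C5", "C3", "C1", "Cz", "C2", "C4", "C6"),
    CP = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"),
    P  = c("P5", "P3", "P1", "Pz", "P2", "P4", "P6")
  )
  region <- c(
    rep("frontal", length(rows$F) + length(rows$FC)),
    rep("other", length(rows$C)),
    rep("parietal", length(rows$CP) + length(rows$P))
  )
  montage(unlist(rows, use.names = FALSE), region)
}

#' @export
print.pk_montage <- function(x, ...) {
  cat(sprintf("<montage: %d channels (%d frontal, %d parietal, %d other)>\n",
              nrow(x), sum(x$region == "frontal"), sum(x$region == "parietal"),
              sum(x$region == "other")))
  cat(" ", paste(x$channel, collapse = " "), "\n")
  invisible(x)
}

validate_montage <- function(m, n_channels = NULL, need_regions = FALSE) {
  if (!inherits(m, "pk_montage")) pk_stop("not a montage object")
  if (!is.null(n_channels) && nrow(m) != n_channels) {
    pk_stop("montage has %d channels but the recording has %d", nrow(m), n_channels)
  }
  if (need_regions &&
      (!any(m$region == "frontal") || !any(m$region == "parietal"))) {
    pk_stop("representative-channel selection needs at least one frontal and one parietal channel")
  }
  invisible(m)
}
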