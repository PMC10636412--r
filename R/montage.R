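#' Load an electrode montage with frontal clusters
#'
#' A montage maps channel labels to schematic 2-D scalp positions and marks
#' the seven-electrode clusters surrounding the F3 (left) and F4 (right)
#' frontal locations. The package ships a 128-channel schematic layout as
#' `inst/extdata/montage128.csv`; any CSV with columns `label,x,y,cluster`
#' (cluster one of `"L"`, `"R"`, `""`) can be used instead.
#'
#' Channel adjacency, used for bad-channel interpolation, is derived from the
#' positions: each channel's neighbours are its `k` nearest channels,
#' symmetrised (if a is a neighbour of b, b is a neighbour of a).
#'
#' @param path CSV file; default is the shipped 128-channel layout.
#' @param k number of nearest neighbours used to build the adjacency.
#' @return an object of class `eeg_montage`: list with `labels`, `pos`
#'   (matrix with columns x, y), `left`/`right` (7 labels each), and
#'   `neighbors` (named list of character vectors).
#' @export
read_montage <- function(path = system.file("extdata", "montage128.csv",
                                            package = "infasym"),
                         k = 4L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "cluster")
  if (!all(need %in% names(df)))
    stop("montage file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$label))
    stop("montage has duplicate labels: ",
         df$label[duplicated(df$label)][1])
  left <- df$label[df$cluster == "L"]
  right <- df$label[df$cluster == "R"]
  if (length(left) != 7L || length(right) != 7L)
    stop("montage must define exactly 7 channels per frontal cluster (got ",
         length(left), " left, ", length(right), " right)")
  pos <- cbind(x = df$x, y = df$y)
  rownames(pos) <- df$label
  m <- structure(
    list(labels = df$label, pos = pos, left = left, right = right,
         neighbors = .montage_neighbors(pos, k)),
    class = "eeg_montage")
  m
}

# k-nearest-neighbour adjacency from 2-D positions, symmetrised
.montage_neighbors <- function(pos, k) {
  n <- nrow(pos)
  labs <- rownames(pos)
  d <- as.matrix(stats::dist(pos))
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    labs[setdiff(ord, i)[seq_len(min(k, n - 1L))]]
  })
  names(nb) <- labs
  # symmetrise
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(labs[i] %in% nb[[j]]))
        nb[[j]] <- c(nb[[j]], labs[i])
    }
  }
  nb
}

#' Restrict a montage to a subset of channels
#'
#' Keeps the 14 frontal-cluster channels plus evenly spaced channels from the
#' remainder until `n_channels` are selected. Used by the synthetic generator
#' when simulating fewer than the full 128 channels (e.g., in fast tests).
#'
#' @param montage an `eeg_montage`.
#' @param n_channels total channels to keep (>= 14).
#' @return an `eeg_montage` with `n_channels` channels.
#' @export
montage_subset <- function(montage, n_channels) {
  stopifnot(inherits(montage, "eeg_montage"))
  core <- c(montage$left, montage$right)
  if (n_channels < length(core))
    stop("n_channels must be >= ", length(core),
         " to retain both frontal clusters")
  if (n_channels >= length(montage$labels)) return(montage)
  rest <- setdiff(montage$labels, core)
  n_extra <- n_channels - length(core)
  keep_rest <- if (n_extra > 0L)
    rest[unique(round(seq(1L, length(rest), length.out = n_extra)))]
  else character()
  keep <- montage$labels[montage$labels %in% c(core, keep_rest)]
  pos <- montage$pos[keep, , drop = FALSE]
  structure(
    list(labels = keep, pos = pos, left = montage$left,
         right = montage$right,
         neighbors = .montage_neighbors(pos, 4L)),
    class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " channels\n",
      "  left cluster:  ", paste(x$left, collapse = " "), "\n",
      "  right cluster: ", paste(x$right, collapse = " "), "\n", sep = "")
  invisible(x)
}
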