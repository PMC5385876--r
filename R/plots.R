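#' Dendrogram of a fingerprint clustering
#'
#' Draws the average-linkage tree on the rescaled 0-25 distance axis, with
#' the class-forming cut shown as a dashed line.
#'
#' @param object A `fingerprint_clusters` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fingerprint_clusters <- function(object, ...) {
  hc <- object$hclust
  seg <- dendrogram_segments(hc)
  labs <- tibble::tibble(x = seq_along(hc$order),
                         label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_hline(yintercept = object$cut, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "rescaled distance (0-25)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}

# leaf/merge coordinates of an hclust tree as plottable segments
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- list()
  pos <- function(id) {
    if (id < 0) c(x = unname(leaf_x[as.character(-id)]), h = 0)
    else c(x = node_x[id], h = node_h[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1])
    b <- pos(hc$merge[i, 2])
    node_x[i] <- (a["x"] + b["x"]) / 2
    h <- node_h[i]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(a["x"], b["x"], a["x"]),
      y = c(a["h"], b["h"], h),
      xend = c(a["x"], b["x"], b["x"]),
      yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}
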