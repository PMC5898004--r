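# Static figure renderers: repository time series, release-by-model change
# heat matrix, and the paired delta-composition boxplots. Deterministic:
# fixed ordering, no timestamps embedded (SVG output).

#' Plot repository evolution time series
#'
#' Two panels: number of models over time and mean element nodes per model,
#' one line per repository.
#'
#' @param repo_evolution From [build_repo_evolution()].
#' @param file Output file (.svg or .png); `NULL` draws on current device.
#' @return `file`, invisibly.
#' @export
plot_repo_evolution <- function(repo_evolution, file = NULL) {
  open_dev(file, width = 10, height = 4.5)
  on.exit(if (!is.null(file)) grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  repos <- setdiff(sort(unique(repo_evolution$repository)), "combined")
  cols <- stats::setNames(seq_along(repos) + 1L, repos)
  dat <- repo_evolution[repo_evolution$repository != "combined", ]
  graphics::plot(range(dat$date), range(dat$models), type = "n",
                 xlab = "date", ylab = "models", main = "Number of models")
  for (r in repos) {
    s <- dat[dat$repository == r, ]
    graphics::lines(s$date, s$models, col = cols[[r]], lwd = 2)
  }
  graphics::legend("topleft", legend = repos, col = cols, lwd = 2, bty = "n")
  mean_nodes <- ifelse(dat$models > 0, dat$nodes / pmax(dat$models, 1L), NA)
  graphics::plot(range(dat$date), range(mean_nodes, na.rm = TRUE), type = "n",
                 xlab = "date", ylab = "mean nodes / model",
                 main = "Mean model size")
  for (r in repos) {
    s <- dat[dat$repository == r, ]
    graphics::lines(s$date, ifelse(s$models > 0, s$nodes / pmax(s$models, 1), NA),
                    col = cols[[r]], lwd = 2)
  }
  invisible(file)
}

#' Plot the release-by-model change heat matrix
#'
#' @param change_matrix From [summarize_evolution()].
#' @inheritParams plot_repo_evolution
#' @export
plot_change_matrix <- function(change_matrix, file = NULL) {
  open_dev(file, width = 8, height = 5)
  on.exit(if (!is.null(file)) grDevices::dev.off())
  if (!length(change_matrix)) {
    graphics::plot.new(); graphics::title("no transitions")
    return(invisible(file))
  }
  m <- log1p(t(change_matrix))  # models on x, releases on y
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                  xlab = "model", ylab = "release transition",
                  main = "Changes per model and release (log scale)",
                  axes = FALSE)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 1,
                 cex.axis = 0.6)
  invisible(file)
}

#' Paired boxplots of delta composition
#'
#' Left: share of each op type per transition; right: share of each XML
#' entity kind — split by repository, mirroring the SBML-vs-CellML contrast
#' view.
#'
#' @param deltas List of `delta` objects.
#' @param repositories Character vector aligned with `deltas` (group label
#'   per delta).
#' @inheritParams plot_repo_evolution
#' @export
plot_delta_boxplots <- function(deltas, repositories, file = NULL) {
  open_dev(file, width = 10, height = 5)
  on.exit(if (!is.null(file)) grDevices::dev.off())
  frac <- op_fractions(deltas)
  frac$repo <- repositories
  graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  long <- function(cols) {
    d <- do.call(rbind, lapply(cols, function(cn)
      data.frame(group = paste(frac$repo, cn, sep = "\n"), value = frac[[cn]])))
    d[!is.na(d$value), ]
  }
  d1 <- long(OP_TYPES)
  graphics::boxplot(value ~ group, data = d1, las = 2, cex.axis = 0.7,
                    ylab = "fraction of ops", main = "Op types")
  d2 <- long(ENTITY_KINDS)
  graphics::boxplot(value ~ group, data = d2, las = 2, cex.axis = 0.7,
                    ylab = "fraction of ops", main = "XML entities")
  invisible(file)
}

# per-delta fractions of each op type and entity kind (NA for empty deltas)
op_fractions <- function(deltas) {
  rows <- lapply(deltas, function(d) {
    s <- d$summary$by_type_kind
    tot <- sum(s)
    r <- c(if (tot > 0) rowSums(s) / tot else rep(NA_real_, nrow(s)),
           if (tot > 0) colSums(s) / tot else rep(NA_real_, ncol(s)))
    as.data.frame(as.list(r))
  })
  out <- do.call(rbind, rows)
  names(out) <- c(OP_TYPES, ENTITY_KINDS)
  out
}

open_dev <- function(file, width, height) {
  if (is.null(file)) return(invisible(NULL))
  if (grepl("\\.png$", file)) grDevices::png(file, width * 96, height * 96)
  else grDevices::svg(file, width = width, height = height)
}
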