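#' @export
print.rigid_domains <- function(x, ...) {
  K <- length(x$domains)
  cat("Rigid-domain segmentation\n")
  cat("  ", length(x$labels), " residues, ", dim(x$ensemble$coords)[1],
      " conformations\n", sep = "")
  cat("  ", K, " domain", if (K != 1) "s", " (delta = ", x$config$delta,
      " A, theta = ", x$config$theta, " A)\n", sep = "")
  for (d in seq_len(K)) {
    cat(sprintf("  domain %d: %4d residues, ensemble RMSD %s A%s\n", d,
                length(x$domains[[d]]),
                formatC(x$domain_rmsd[d], digits = 2, format = "f"),
                if (isTRUE(x$non_rigid[d])) "  [non-rigid]" else ""))
  }
  if (length(x$warnings)) cat("  warnings: ", length(x$warnings), "\n", sep = "")
  invisible(x)
}

#' Summarise a rigid-domain segmentation
#'
#' @param object A \code{rigid_domains} fit.
#' @param ... Unused.
#' @return An object of class \code{summary.rigid_domains} with a per-domain
#'   table (size, residue ranges in author numbering, ensemble RMSD) and
#'   pipeline diagnostics.
#' @export
summary.rigid_domains <- function(object, ...) {
  ids <- object$residue_ids
  ranges <- vapply(object$domains, function(s) {
    r <- ids$resno[s]
    runs <- split(r, cumsum(c(1, diff(r) != 1)))
    paste(vapply(runs, function(z)
      if (length(z) == 1) as.character(z) else paste0(z[1], "-", z[length(z)]),
      character(1)), collapse = ",")
  }, character(1))
  tab <- data.frame(domain = seq_along(object$domains),
                    size = lengths(object$domains),
                    residues = ranges,
                    rmsd = round(object$domain_rmsd, 3),
                    non_rigid = object$non_rigid)
  structure(list(table = tab,
                 n_domains = length(object$domains),
                 n_communities = object$n_communities,
                 resolution = object$resolution,
                 n_edges = object$n_edges,
                 config = object$config,
                 warnings = object$warnings),
            class = "summary.rigid_domains")
}

#' @export
print.summary.rigid_domains <- function(x, ...) {
  cat("Rigid-domain segmentation summary\n")
  cat("  protein graph: ", x$n_edges, " edges; coarse graph: ",
      x$n_communities, " communities (resolution ",
      formatC(x$resolution, digits = 3, format = "g"), ")\n", sep = "")
  print(x$table, row.names = FALSE)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.rigid_domains <- function(x, ...) {
  cbind(x$residue_ids, domain = x$labels)
}

#' @export
labels.rigid_domains <- function(object, ...) object$labels

#' Plot a rigid-domain segmentation along the chain
#'
#' Residue index against domain id, colored by domain, with per-domain
#' ensemble RMSDs in the legend.
#'
#' @param x A \code{rigid_domains} fit.
#' @param ... Passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.rigid_domains <- function(x, ...) {
  K <- length(x$domains)
  cols <- grDevices::hcl.colors(max(K, 3), "Dark 3")
  graphics::plot(seq_along(x$labels), x$labels, type = "n",
                 xlab = "residue index", ylab = "domain",
                 yaxt = "n", ylim = c(0.5, K + 0.5), ...)
  graphics::axis(2, at = seq_len(K))
  graphics::points(seq_along(x$labels), x$labels, pch = 15,
                   col = cols[x$labels], cex = 0.6)
  graphics::legend("topleft", bty = "n", pch = 15, col = cols[seq_len(K)],
                   legend = sprintf("domain %d (RMSD %.2f A)", seq_len(K),
                                    x$domain_rmsd))
  invisible(x)
}

#' Run report of a segmentation as JSON
#'
#' Serialises the effective parameters, per-domain residue ranges (author
#' numbering) and RMSDs, a recursion summary, and any warnings. Re-loadable
#' with \code{jsonlite::read_json}.
#'
#' @param fit A \code{rigid_domains} fit.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to \code{path}).
#' @export
run_report <- function(fit, path = NULL) {
  s <- summary(fit)
  rep <- list(
    parameters = unclass(fit$config),
    rule = fit$rule,
    n_domains = s$n_domains,
    domains = lapply(seq_len(nrow(s$table)), function(i) list(
      domain = s$table$domain[i], size = s$table$size[i],
      residues = s$table$residues[i], rmsd = s$table$rmsd[i],
      non_rigid = s$table$non_rigid[i])),
    recursion = list(
      n_nodes = length(fit$tree),
      max_depth = if (length(fit$tree))
        max(vapply(fit$tree, `[[`, 1, "depth")) else 0L,
      n_splits = sum(vapply(fit$tree, function(n)
        !isTRUE(n$leaf), logical(1)))),
    coarse_graph = list(n_communities = fit$n_communities,
                        resolution = fit$resolution),
    warnings = fit$warnings)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
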