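#' Two-moons point cloud
#'
#' Generates the standard interleaved half-circle benchmark: moon 0 follows
#' `(cos theta, sin theta)` and moon 1 follows
#' `(1 - cos theta, 0.5 - sin theta)` with `theta ~ U[0, pi]`, plus isotropic
#' Gaussian noise. Defaults are 200 examples per class with noise standard
#' deviation 0.1.
#'
#' @param n_per_class Examples per moon.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return Tibble with `x1`, `x2` and zero-based `label`.
#' @export
make_two_moons <- function(n_per_class = 200L, noise_sigma = 0.1, seed = 1L) {
  stopifnot(n_per_class >= 1L, noise_sigma >= 0)
  with_seed(seed, {
    th0 <- stats::runif(n_per_class, 0, pi)
    th1 <- stats::runif(n_per_class, 0, pi)
    pts <- rbind(cbind(cos(th0), sin(th0)),
                 cbind(1 - cos(th1), 0.5 - sin(th1)))
    pts <- pts + matrix(stats::rnorm(2 * 2 * n_per_class, sd = noise_sigma),
                        ncol = 2)
    tibble::tibble(x1 = pts[, 1], x2 = pts[, 2],
                   label = rep(0:1, each = n_per_class))
  })
}

#' Regular evaluation grid
#'
#' A `resolution x resolution` grid over rectangular bounds (corners
#' included), used to probe predictive confidence away from the training data.
#'
#' @param bounds Either `c(lo, hi)` applied to both dimensions or a list
#'   `list(x1 = c(lo, hi), x2 = c(lo, hi))`.
#' @param resolution Points per axis (>= 2).
#' @return Tibble with `x1`, `x2`.
#' @export
make_ood_grid <- function(bounds = c(-3, 3), resolution = 10L) {
  stopifnot(resolution >= 2L)
  if (!is.list(bounds)) bounds <- list(x1 = bounds, x2 = bounds)
  g1 <- seq(bounds$x1[1], bounds$x1[2], length.out = resolution)
  g2 <- seq(bounds$x2[1], bounds$x2[2], length.out = resolution)
  tidyr::expand_grid(x1 = g1, x2 = g2)
}

#' Far-field subset of an evaluation grid
#'
#' Keeps the grid points whose Euclidean distance to every training point
#' exceeds `min_dist`.
#'
#' @param grid Tibble with `x1`, `x2` (from [make_ood_grid()]).
#' @param train_points Matrix or data frame of training coordinates.
#' @param min_dist Distance threshold (default 3).
#' @return The far-field subset of `grid`.
#' @export
far_field_points <- function(grid, train_points, min_dist = 3) {
  tp <- as.matrix(train_points)[, 1:2, drop = FALSE]
  gp <- as.matrix(grid[, c("x1", "x2")])
  keep <- vapply(seq_len(nrow(gp)), function(i) {
    min(sqrt((tp[, 1] - gp[i, 1])^2 + (tp[, 2] - gp[i, 2])^2)) > min_dist
  }, logical(1))
  grid[keep, , drop = FALSE]
}

#' Spike-template task stream
#'
#' A desk-scale stand-in for split-class continual benchmarks: each class is
#' assigned a fixed binary template raster, examples are the template with
#' i.i.d. bit flips, and tasks present the classes in consecutive pairs (or
#' groups of `classes_per_task`) in index order. With
#' `template_mode = "orthogonal"` the (neuron, time) cells are partitioned at
#' random among the classes and each template fires only inside its own cell
#' set, so templates are pairwise orthogonal (no co-active cell) while every
#' neuron still participates in several classes; `"random"` draws i.i.d.
#' Bernoulli(`template_density`) templates.
#'
#' @param n_classes Total classes (divisible by `classes_per_task`).
#' @param classes_per_task Classes presented per task (default 2).
#' @param n_neurons,T Template raster geometry.
#' @param template_density Firing probability inside a template.
#' @param flip_prob Per-bit corruption probability, in \[0, 0.5).
#' @param n_train,n_test Examples per class.
#' @param template_mode `"random"` or `"orthogonal"`.
#' @param seed Integer seed.
#' @return A `task_stream`: list of tasks (`train`/`test` `spike_dataset`s and
#'   the zero-based `classes` they contain), plus the class `templates` and
#'   the generating parameters.
#' @export
make_template_stream <- function(n_classes = 4L, classes_per_task = 2L,
                                 n_neurons = 30L, T = 20L,
                                 template_density = 0.3, flip_prob = 0.05,
                                 n_train = 40L, n_test = 20L,
                                 template_mode = c("random", "orthogonal"),
                                 seed = 1L) {
  template_mode <- match.arg(template_mode)
  if (n_classes %% classes_per_task != 0L) {
    stop("`n_classes` must be divisible by `classes_per_task`", call. = FALSE)
  }
  if (flip_prob < 0 || flip_prob >= 0.5) {
    stop("`flip_prob` must lie in [0, 0.5)", call. = FALSE)
  }
  with_seed(seed, {
    templates <- if (template_mode == "orthogonal") {
      # partition cells among classes; fire within own cells at a rate that
      # keeps the expected per-template density at template_density
      owner <- matrix(sample.int(n_classes, n_neurons * T, replace = TRUE),
                      n_neurons, T)
      lapply(seq_len(n_classes), function(cl) {
        tmpl <- matrix(0, n_neurons, T)
        cells <- which(owner == cl)
        tmpl[cells] <- stats::rbinom(length(cells), 1L,
                                     min(1, n_classes * template_density))
        tmpl
      })
    } else {
      lapply(seq_len(n_classes), function(cl) {
        repeat {
          tmpl <- matrix(stats::rbinom(n_neurons * T, 1L, template_density),
                         n_neurons, T)
          if (sum(tmpl) > 0) break
        }
        tmpl
      })
    }
    corrupt <- function(tmpl, n) {
      x <- array(0, c(n_neurons, T, n))
      for (i in seq_len(n)) {
        flips <- matrix(stats::rbinom(n_neurons * T, 1L, flip_prob), n_neurons, T)
        x[, , i] <- abs(tmpl - flips)
      }
      x
    }
    n_tasks <- n_classes %/% classes_per_task
    tasks <- lapply(seq_len(n_tasks), function(k) {
      classes <- (k - 1L) * classes_per_task + seq_len(classes_per_task) - 1L
      mk <- function(n_per) {
        xs <- lapply(classes, function(cl) corrupt(templates[[cl + 1L]], n_per))
        x <- array(c(sapply(xs, identity)), c(n_neurons, T, n_per * length(classes)))
        spike_dataset(x, rep(classes, each = n_per), n_classes = n_classes)
      }
      list(train = mk(n_train), test = mk(n_test), classes = classes)
    })
    structure(list(tasks = tasks, templates = templates,
                   n_classes = as.integer(n_classes),
                   classes_per_task = as.integer(classes_per_task),
                   flip_prob = flip_prob, template_density = template_density,
                   template_mode = template_mode, seed = as.integer(seed)),
              class = "task_stream")
  })
}

#' @export
print.task_stream <- function(x, ...) {
  cat(sprintf("<task_stream: %d tasks x %d classes each (%s templates, flip %.2f)>\n",
              length(x$tasks), x$classes_per_task, x$template_mode, x$flip_prob))
  invisible(x)
}
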