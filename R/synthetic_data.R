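#' Multitask dataset container
#'
#' A feature matrix with one binary labelling per task plus fixed
#' train/test splits. Rows of `X` are samples, columns are features.
#'
#' @param X Numeric matrix (samples x features).
#' @param labels Named list; one 0/1 integer vector per task, each of
#'   length `nrow(X)`.
#' @param train_idx,test_idx Integer row indices of the two splits.
#' @param metadata List with at least `generator` and `seed`.
#' @return An object of class `multitask_dataset`.
#' @export
multitask_dataset <- function(X, labels, train_idx, test_idx, metadata = list()) {
  obj <- structure(
    list(X = X, labels = labels, train_idx = as.integer(train_idx),
         test_idx = as.integer(test_idx), metadata = metadata),
    class = "multitask_dataset"
  )
  validate_multitask_dataset(obj)
  obj
}

#' Validate a multitask dataset
#'
#' Checks the container invariants: label vectors match the sample count,
#' labels are binary, splits are disjoint and in range, and every task has
#' both classes in every split.
#'
#' @param data A `multitask_dataset`.
#' @return `data`, invisibly; errors on violation.
#' @export
validate_multitask_dataset <- function(data) {
  stopifnot(inherits(data, "multitask_dataset"))
  n <- nrow(data$X)
  if (is.null(names(data$labels)) || any(names(data$labels) == ""))
    dm_stop("dm_invalid_dataset", "tasks must be named")
  for (t in names(data$labels)) {
    y <- data$labels[[t]]
    if (length(y) != n)
      dm_stop("dm_invalid_dataset", "labels for task '%s' have length %d, expected %d",
              t, length(y), n)
    if (!all(y %in% c(0L, 1L)))
      dm_stop("dm_invalid_dataset", "labels for task '%s' are not binary", t)
  }
  idx <- c(data$train_idx, data$test_idx)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > n))
    dm_stop("dm_invalid_dataset", "train/test splits overlap or are out of range")
  for (t in names(data$labels)) {
    for (split in list(train = data$train_idx, test = data$test_idx)) {
      cls <- unique(data$labels[[t]][split])
      if (length(cls) < 2L)
        dm_stop("dm_degenerate_task",
                "task '%s' has a single class in one split", t)
    }
  }
  invisible(data)
}

#' @export
print.multitask_dataset <- function(x, ...) {
  cat(sprintf("<multitask_dataset> %d samples x %d features, %d tasks (%d train / %d test)\n",
              nrow(x$X), ncol(x$X), length(x$labels),
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Generate a two-dimensional multitask classification set
#'
#' Samples points uniformly in the square `[-1, 1]^2` and labels them, per
#' task, by the sign of a random quadratic form, producing 48 varied
#' nonlinear decision boundaries by default. Boundaries leaving a minority
#' class below 25% are resampled.
#'
#' @param n_tasks Number of binary tasks (default 48).
#' @param n_samples Number of 2D points shared by all tasks.
#' @param seed Integer seed; the dataset is bit-reproducible given the seed.
#' @param train_frac Fraction of samples in the training split.
#' @param max_retries Boundary resampling attempts per task before erroring.
#' @return A [multitask_dataset()].
#' @export
gen_2d_multitask <- function(n_tasks = 48L, n_samples = 600L, seed = 1L,
                             train_frac = 0.75, max_retries = 100L) {
  stopifnot(n_tasks >= 1L, n_samples >= 8L)
  with_seed(seed, {
    X <- cbind(runif(n_samples, -1, 1), runif(n_samples, -1, 1))
    colnames(X) <- c("x1", "x2")
    ord <- sample.int(n_samples)
    n_train <- max(2L, round(train_frac * n_samples))
    train_idx <- ord[seq_len(n_train)]
    test_idx <- ord[-seq_len(n_train)]
    labels <- list()
    for (t in seq_len(n_tasks)) {
      ok <- FALSE
      for (attempt in seq_len(max_retries)) {
        a <- rnorm(5)
        a0 <- rnorm(1, sd = 0.4)
        f <- a0 + a[1] * X[, 1] + a[2] * X[, 2] +
          a[3] * X[, 1]^2 + a[4] * X[, 2]^2 + a[5] * X[, 1] * X[, 2]
        y <- as.integer(f > 0)
        balanced <- function(idx) {
          p <- mean(y[idx]); min(p, 1 - p) >= 0.25
        }
        if (balanced(train_idx) && balanced(test_idx)) { ok <- TRUE; break }
      }
      if (!ok)
        dm_stop("dm_unbalanceable_task",
                "could not draw a balanced boundary for task %d", t)
      labels[[sprintf("task%02d", t)]] <- y
    }
    multitask_dataset(X, labels, train_idx, test_idx,
                      metadata = list(generator = "gen_2d_multitask", seed = seed))
  })
}

# render one glyph: max over strokes of a Gaussian pen profile around each
# line segment, on an image_size x image_size grid over the unit square
render_strokes <- function(strokes, image_size, pen = 0.06) {
  g <- (seq_len(image_size) - 0.5) / image_size
  px <- matrix(rep(g, each = image_size), ncol = 1)   # x per pixel (col-major)
  py <- matrix(rep(g, times = image_size), ncol = 1)
  img <- matrix(0, image_size, image_size)
  for (s in strokes) {
    vx <- s[3] - s[1]; vy <- s[4] - s[2]
    L2 <- vx * vx + vy * vy
    tt <- if (L2 > 0) pmin(pmax(((px - s[1]) * vx + (py - s[2]) * vy) / L2, 0), 1) else 0
    dx <- px - (s[1] + tt * vx); dy <- py - (s[2] + tt * vy)
    d2 <- dx * dx + dy * dy
    img <- pmax(img, matrix(exp(-d2 / (2 * pen^2)), image_size, image_size))
  }
  img
}

#' Generate procedurally rendered glyph images
#'
#' A stand-in for handwritten-character datasets that needs no download:
#' each class is a fixed template of 2--4 strokes in the unit square;
#' samples jitter the template (rotation, translation, endpoint noise) and
#' add pixel noise. Intensities lie in `[0, 1]`.
#'
#' @param n_classes Number of glyph classes (>= 2).
#' @param image_size Side length in pixels (>= 6).
#' @param n_per_class Samples rendered per class.
#' @param seed Integer seed.
#' @param noise_sd Pixel noise standard deviation.
#' @return List with `X` (n x image_size^2 matrix, row-major pixel order),
#'   `class` (integer class per row), `image_size`, `seed`.
#' @export
gen_glyph_images <- function(n_classes, image_size = 16L, n_per_class = 40L,
                             seed = 1L, noise_sd = 0.02) {
  if (n_classes < 2L) dm_stop("dm_config_error", "need at least 2 glyph classes")
  if (image_size < 6L) dm_stop("dm_config_error", "image_size too small to render strokes")
  d <- image_size^2
  templates <- lapply(seq_len(n_classes), function(c) {
    with_seed(derive_seed(seed, paste0("glyph_template_", c)), {
      k <- sample(2:4, 1)
      lapply(seq_len(k), function(i) runif(4, 0.15, 0.85))
    })
  })
  with_seed(derive_seed(seed, "glyph_samples"), {
    n <- n_classes * n_per_class
    X <- matrix(0, n, d)
    cls <- integer(n)
    row <- 0L
    for (c in seq_len(n_classes)) {
      for (i in seq_len(n_per_class)) {
        row <- row + 1L
        th <- rnorm(1, sd = 10 * pi / 180)
        shift <- rnorm(2, sd = 0.04)
        strokes <- lapply(templates[[c]], function(s) {
          s <- s + rnorm(4, sd = 0.015)
          rot <- function(x, y) {
            xc <- x - 0.5; yc <- y - 0.5
            c(0.5 + cos(th) * xc - sin(th) * yc + shift[1],
              0.5 + sin(th) * xc + cos(th) * yc + shift[2])
          }
          p1 <- rot(s[1], s[2]); p2 <- rot(s[3], s[4])
          c(p1, p2)
        })
        img <- render_strokes(strokes, image_size)
        img <- img + matrix(rnorm(d, sd = noise_sd), image_size, image_size)
        X[row, ] <- pmin(pmax(as.vector(t(img)), 0), 1)
        cls[row] <- c
      }
    }
    list(X = X, class = cls, image_size = as.integer(image_size), seed = seed)
  })
}

#' Convert a labelled multiclass set to a one-vs-all multitask problem
#'
#' One binary task per class: positives are that class, negatives all other
#' classes. The split is stratified by class so every task keeps both
#' labels in both splits.
#'
#' @param labeled List with `X` and `class` as from [gen_glyph_images()].
#' @param train_frac Fraction of each class in the training split.
#' @param seed Seed for the stratified split.
#' @return A [multitask_dataset()] with one task per class.
#' @export
to_one_vs_all <- function(labeled, train_frac = 0.75, seed = 1L) {
  cls <- labeled$class
  classes <- sort(unique(cls))
  if (length(classes) < 2L) dm_stop("dm_config_error", "need >= 2 classes")
  with_seed(derive_seed(seed, "ova_split"), {
    train_idx <- integer(0)
    for (c in classes) {
      rows <- which(cls == c)
      rows <- sample(rows)
      k <- max(1L, min(length(rows) - 1L, round(train_frac * length(rows))))
      train_idx <- c(train_idx, rows[seq_len(k)])
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(cls), train_idx)
    labels <- lapply(classes, function(c) as.integer(cls == c))
    names(labels) <- sprintf("class%02d", classes)
    multitask_dataset(labeled$X, labels, train_idx, test_idx,
                      metadata = list(generator = "to_one_vs_all",
                                      seed = seed,
                                      image_size = labeled$image_size))
  })
}

#' Balanced batch sampler
#'
#' Builds one epoch of batches from the training split. Each batch covers
#' `tasks_per_batch` tasks; within a batch every included task contributes
#' the same number of samples, split equally between its positive and
#' negative class. Minority classes (e.g. one-vs-all positives) are
#' oversampled with replacement to meet the balance.
#'
#' @param data A [multitask_dataset()].
#' @param batch_size Total samples per batch; must be divisible by
#'   `2 * tasks_per_batch`.
#' @param seed Integer seed; batches are deterministic given the seed.
#' @param tasks_per_batch Tasks per batch; default: the largest divisor of
#'   `batch_size / 2` not exceeding the task count.
#' @param n_epoch_batches Number of batches; default cycles each task once.
#' @return List of batches, each a data.frame with columns `task_id`,
#'   `idx` (row in `data$X`), `y`.
#' @export
balanced_batches <- function(data, batch_size, seed, tasks_per_batch = NULL,
                             n_epoch_batches = NULL) {
  tasks <- names(data$labels)
  if (is.null(tasks_per_batch)) {
    cand <- seq_len(min(length(tasks), batch_size %/% 2L))
    cand <- cand[(batch_size %% (2L * cand)) == 0L]
    if (!length(cand))
      dm_stop("dm_config_error", "batch_size %d cannot be balanced", batch_size)
    tasks_per_batch <- max(cand)
  }
  if (batch_size %% (2L * tasks_per_batch) != 0L)
    dm_stop("dm_config_error",
            "batch_size %d not divisible by 2 * tasks_per_batch = %d",
            batch_size, 2L * tasks_per_batch)
  per_class <- batch_size %/% (2L * tasks_per_batch)
  if (is.null(n_epoch_batches))
    n_epoch_batches <- ceiling(length(tasks) / tasks_per_batch)
  with_seed(seed, {
    order_tasks <- sample(tasks)
    pos <- lapply(data$labels, function(y) intersect(data$train_idx, which(y == 1L)))
    neg <- lapply(data$labels, function(y) intersect(data$train_idx, which(y == 0L)))
    draw <- function(pool, k) {
      if (length(pool) >= k) sample(pool, k) else sample(pool, k, replace = TRUE)
    }
    batches <- vector("list", n_epoch_batches)
    ti <- 0L
    for (b in seq_len(n_epoch_batches)) {
      rows <- list()
      for (j in seq_len(tasks_per_batch)) {
        t <- order_tasks[(ti %% length(tasks)) + 1L]; ti <- ti + 1L
        rows[[j]] <- data.frame(
          task_id = t,
          idx = c(draw(pos[[t]], per_class), draw(neg[[t]], per_class)),
          y = rep(c(1L, 0L), each = per_class),
          stringsAsFactors = FALSE
        )
      }
      batches[[b]] <- do.call(rbind, rows)
    }
    batches
  })
}

#' Read an IDX-format array file
#'
#' Reader for the big-endian IDX byte format used by the classic
#' handwritten-character datasets, for users who have such files locally
#' (nothing in this package requires them). Supports unsigned byte,
#' signed byte, 16/32-bit integer, and 32/64-bit float element types.
#'
#' @param path Path to an (uncompressed) IDX file.
#' @return For 1-D files a vector; for 2-D a matrix; for N-D an array with
#'   the dimensions given in the header (first dimension = items).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 4)
  if (!identical(as.integer(magic[1:2]), c(0L, 0L)))
    dm_stop("dm_input_error", "not an IDX file (bad magic): %s", path)
  type <- as.integer(magic[3])
  n_dim <- as.integer(magic[4])
  dims <- readBin(con, "integer", n_dim, size = 4, endian = "big")
  n <- prod(dims)
  data <- switch(as.character(type),
    "8"  = as.integer(readBin(con, "raw", n)),                    # ubyte
    "9"  = readBin(con, "integer", n, size = 1, endian = "big"),  # sbyte
    "11" = readBin(con, "integer", n, size = 2, endian = "big"),
    "12" = readBin(con, "integer", n, size = 4, endian = "big"),
    "13" = readBin(con, "double", n, size = 4, endian = "big"),
    "14" = readBin(con, "double", n, size = 8, endian = "big"),
    dm_stop("dm_input_error", "unsupported IDX element type 0x%02x", type))
  if (length(data) != n)
    dm_stop("dm_input_error", "truncated IDX file: %s", path)
  if (n_dim == 1L) return(data)
  # IDX stores row-major; R arrays are column-major
  aperm(array(data, dim = rev(dims)), rev(seq_len(n_dim)))
}

#' Generate XOR episodes for the spiking network
#'
#' Each episode carries two binary channels: bit `a` selects which of two
#' feedforward input patterns is delivered as a spike burst, bit `b`
#' selects which of two context channels bursts onto the dendrites. The
#' target is `a XOR b`: the output neuron must spike when the label is 1
#' and stay silent when it is 0 -- a problem that is not linearly separable
#' in the joint (input, context) space.
#'
#' @param n_episodes Number of episodes.
#' @param seed Integer seed.
#' @return data.frame with columns `a`, `b`, `label`, in presentation order.
#' @export
gen_xor_episodes <- function(n_episodes, seed = 1L) {
  stopifnot(n_episodes >= 1L)
  with_seed(seed, {
    combos <- expand.grid(a = 0:1, b = 0:1)
    reps <- n_episodes %/% 4L
    rows <- rep(seq_len(4L), reps)
    extra <- n_episodes - length(rows)
    if (extra > 0) rows <- c(rows, sample.int(4L, extra, replace = TRUE))
    rows <- sample(rows)
    out <- combos[rows, , drop = FALSE]
    out$label <- as.integer(xor(out$a == 1L, out$b == 1L))
    rownames(out) <- NULL
    out
  })
}
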