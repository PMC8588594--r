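# Discrete design space of virtual subjects: enumeration, encoding,
# stratified (Latin-hypercube style) subsampling and train/test splitting.

#' Grid specification for the virtual-subject design space
#'
#' Returns the list of factor levels defining the full-factorial space of
#' virtual subjects. The defaults are the canonical study levels: two sexes,
#' five ages (28--68 years), three weight classes, three height classes, a
#' physical-activity pattern (0--3 sessions/week of 30/60/90 minutes at
#' 40/60 %VO2max), and low/med/high per-meal carbohydrate, protein and fat
#' levels. Any factor can be restricted by name.
#'
#' @param ... named character/numeric vectors overriding individual factors
#'   (e.g. `pa_sessions = 0`).
#' @return A named list of levels, one entry per subject field, in canonical
#'   field order.
#' @examples
#' spec <- grid_spec(pa_sessions = 0)
#' nrow(enumerate_grid(spec))  # 2430
#' @export
grid_spec <- function(...) {
  override <- list(...)
  unknown <- setdiff(names(override), .subject_fields)
  if (length(unknown) > 0) {
    stopf("unknown grid factor(s): %s", paste(unknown, collapse = ", "))
  }
  spec <- .default_levels
  for (nm in names(override)) {
    lev <- override[[nm]]
    if (length(lev) == 0) stopf("empty level list for factor '%s'", nm)
    bad <- setdiff(lev, .default_levels[[nm]])
    if (length(bad) > 0) {
      stopf("invalid level(s) for '%s': %s", nm, paste(bad, collapse = ", "))
    }
    spec[[nm]] <- lev
  }
  spec
}

# physical-activity block: sessions = 0 collapses duration/intensity to the
# 0/0 sentinel (they are undefined without exercise); this is what makes the
# default grid total 90 * 19 * 27 = 46170 rather than 90 * 24 * 27
.pa_block <- function(spec) {
  blocks <- list()
  sessions <- sort(spec$pa_sessions)
  if (0 %in% sessions) {
    blocks[[1]] <- data.frame(pa_sessions = 0, pa_duration = 0, pa_intensity = 0)
  }
  active <- sessions[sessions > 0]
  if (length(active) > 0) {
    g <- expand.grid(
      pa_intensity = sort(spec$pa_intensity),
      pa_duration  = sort(spec$pa_duration),
      pa_sessions  = active,
      KEEP.OUT.ATTRS = FALSE
    )
    blocks[[length(blocks) + 1]] <- g[, c("pa_sessions", "pa_duration", "pa_intensity")]
  }
  pa <- do.call(rbind, blocks)
  pa[order(pa$pa_sessions, pa$pa_duration, pa$pa_intensity), , drop = FALSE]
}

# cross join preserving lexicographic order: `left` varies slowest
.cross_join <- function(left, right) {
  nl <- nrow(left); nr <- nrow(right)
  out <- cbind(
    left[rep(seq_len(nl), each = nr), , drop = FALSE],
    right[rep(seq_len(nr), times = nl), , drop = FALSE]
  )
  rownames(out) <- NULL
  out
}

#' Enumerate the full factorial grid of virtual subjects
#'
#' Expands a [grid_spec()] into every admissible virtual subject. Rows are in
#' deterministic lexicographic order of the subject fields (level order as
#' listed in the specification, e.g. `low < med < high`), and each row gets a
#' stable `subject_id` equal to its position. With the default specification
#' the grid has exactly 46170 rows: 90 anthropometric combinations times 19
#' physical-activity patterns (1 sedentary sentinel + 3 x 3 x 2 active
#' combinations) times 27 diets.
#'
#' @param spec a grid specification from [grid_spec()].
#' @return A `subject_grid`: a data frame with `subject_id` plus the ten
#'   subject fields.
#' @examples
#' grid <- enumerate_grid()
#' nrow(grid)  # 46170
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  for (nm in .subject_fields) {
    if (length(spec[[nm]]) == 0) stopf("empty level list for factor '%s'", nm)
  }
  ord <- function(nm) {
    lev <- .default_levels[[nm]]
    lev[lev %in% spec[[nm]]]
  }
  anth <- Reduce(
    .cross_join,
    lapply(c("sex", "age", "weight_class", "height_class"), function(nm) {
      stats::setNames(data.frame(ord(nm), stringsAsFactors = FALSE), nm)
    })
  )
  diet <- Reduce(
    .cross_join,
    lapply(c("carb_level", "prot_level", "fat_level"), function(nm) {
      stats::setNames(data.frame(ord(nm), stringsAsFactors = FALSE), nm)
    })
  )
  grid <- .cross_join(.cross_join(anth, .pa_block(spec)), diet)
  grid <- cbind(subject_id = seq_len(nrow(grid)), grid)
  attr(grid, "spec") <- spec
  class(grid) <- c("subject_grid", "data.frame")
  grid
}

.check_subjects <- function(subjects) {
  missing <- setdiff(.subject_fields, names(subjects))
  if (length(missing) > 0) {
    stopf("subject table lacks field(s): %s", paste(missing, collapse = ", "))
  }
  for (nm in c("sex", "weight_class", "height_class",
               "carb_level", "prot_level", "fat_level")) {
    bad <- setdiff(unique(subjects[[nm]]), .default_levels[[nm]])
    if (length(bad) > 0) {
      stopf("unknown %s value(s): %s", nm, paste(bad, collapse = ", "))
    }
  }
  sentinel_ok <- subjects$pa_sessions > 0 |
    (subjects$pa_duration == 0 & subjects$pa_intensity == 0)
  if (!all(sentinel_ok)) {
    stopf("pa_sessions = 0 requires the 0/0 duration/intensity sentinel")
  }
  invisible(subjects)
}

#' Encode virtual subjects as numeric feature vectors
#'
#' Maps each subject to a length-10 numeric vector used as regressor input
#' for the tree ensemble. Ordinal fields keep their numeric values (age,
#' sessions, minutes, %VO2max, 0 sentinels); `sex` maps to 0/1
#' (female/male); ordered categories map to rank codes
#' (`underweight/short/low` = 1, ... , `overweight/tall/high` = 3). The
#' mapping is invertible via [decode_subjects()].
#'
#' @param subjects a data frame of subjects (rows of a `subject_grid`).
#' @return A numeric matrix, one row per subject, columns in subject field
#'   order.
#' @export
encode_subjects <- function(subjects) {
  subjects <- as.data.frame(subjects)
  .check_subjects(subjects)
  code <- function(x, nm) {
    lev <- .default_levels[[nm]]
    if (is.character(lev)) {
      m <- match(x, lev)
      if (anyNA(m)) stopf("cannot encode %s value(s)", nm)
      if (nm == "sex") m - 1 else m
    } else {
      as.numeric(x)
    }
  }
  out <- vapply(.subject_fields, function(nm) code(subjects[[nm]], nm),
                numeric(nrow(subjects)))
  if (nrow(subjects) == 1L) out <- matrix(out, nrow = 1,
                                          dimnames = list(NULL, .subject_fields))
  out
}

#' Decode numeric feature vectors back to subject descriptors
#'
#' Inverse of [encode_subjects()].
#'
#' @param x a numeric matrix (or single vector) with columns in subject field
#'   order.
#' @return A data frame of subject descriptors.
#' @export
decode_subjects <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- x[, .subject_fields, drop = FALSE]
  dec <- function(v, nm) {
    lev <- .default_levels[[nm]]
    if (is.character(lev)) {
      idx <- if (nm == "sex") v + 1 else v
      if (any(idx < 1 | idx > length(lev) | idx != round(idx))) {
        stopf("cannot decode %s code(s)", nm)
      }
      lev[idx]
    } else {
      v
    }
  }
  out <- data.frame(row.names = seq_len(nrow(x)))
  for (nm in .subject_fields) out[[nm]] <- dec(x[, nm], nm)
  .check_subjects(out)
  out
}

# composite stratification factors: the three physical-activity fields act as
# one 19-level factor so that marginal balance respects the collapsed grid
.strat_factors <- function(subjects) {
  list(
    sex          = subjects$sex,
    age          = subjects$age,
    weight_class = subjects$weight_class,
    height_class = subjects$height_class,
    pa           = paste(subjects$pa_sessions, subjects$pa_duration,
                         subjects$pa_intensity, sep = "|"),
    carb_level   = subjects$carb_level,
    prot_level   = subjects$prot_level,
    fat_level    = subjects$fat_level
  )
}

.grid_key <- function(subjects) {
  do.call(paste, c(lapply(.subject_fields, function(nm) subjects[[nm]]),
                   sep = "|"))
}

#' Stratified Latin-hypercube style subsample of the subject grid
#'
#' Selects `k` distinct subjects such that, for each stratification factor
#' (the four anthropometric fields, the composite physical-activity pattern,
#' and the three diet levels), the level counts deviate from exact
#' proportionality by at most one subject. This realizes a Latin-hypercube
#' design on the categorical grid: levels are allocated proportionally per
#' factor, matched across factors by seeded random permutation, and duplicate
#' rows are repaired by marginal-preserving swaps.
#'
#' @param grid a `subject_grid` from [enumerate_grid()]. The grid must be
#'   full-factorial in the stratification factors (always true for grids
#'   built by [enumerate_grid()]).
#' @param k number of subjects to select, `1 <= k <= nrow(grid)`.
#' @param seed integer seed; the same seed, grid and size reproduce the
#'   selection exactly.
#' @param scheme `"lhs"` (stratified, default), `"random"` (simple random
#'   subject sample) or `"full"` (the whole grid, `k` ignored).
#' @return A `design_sample`: the selected rows of `grid` (with their
#'   `subject_id`s), with attributes `seed` and `scheme`.
#' @export
lhs_sample <- function(grid, k, seed = 1L, scheme = c("lhs", "random", "full")) {
  scheme <- match.arg(scheme)
  n <- nrow(grid)
  if (scheme == "full") k <- n
  if (k < 1 || k > n) stopf("k must be between 1 and %d (got %s)", n, format(k))
  out <- if (scheme == "random" && k < n) {
    idx <- with_seed(seed, sort(sample.int(n, k)))
    grid[idx, , drop = FALSE]
  } else if (k == n) {
    grid
  } else {
    .lhs_select(grid, k, seed)
  }
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  attr(out, "scheme") <- scheme
  class(out) <- c("design_sample", "data.frame")
  out
}

.lhs_select <- function(grid, k, seed) {
  facs <- .strat_factors(grid)
  with_seed(derive_seed(seed, "lhs"), {
    # proportional allocation with the remainder spread at random, then an
    # independent random matching (permutation) per factor
    cols <- lapply(facs, function(f) {
      lev <- unique(f)
      L <- length(lev)
      counts <- rep(k %/% L, L)
      rem <- k %% L
      if (rem > 0) {
        bump <- sample.int(L, rem)
        counts[bump] <- counts[bump] + 1
      }
      sample(rep(lev, counts))
    })
    cand <- data.frame(
      sex = cols$sex, age = cols$age, weight_class = cols$weight_class,
      height_class = cols$height_class, carb_level = cols$carb_level,
      prot_level = cols$prot_level, fat_level = cols$fat_level,
      stringsAsFactors = FALSE
    )
    pa <- do.call(rbind, strsplit(cols$pa, "|", fixed = TRUE))
    cand$pa_sessions  <- as.numeric(pa[, 1])
    cand$pa_duration  <- as.numeric(pa[, 2])
    cand$pa_intensity <- as.numeric(pa[, 3])
    cand <- cand[, .subject_fields]

    # repair duplicates by swapping one factor between a duplicated row and a
    # random partner: marginal counts are invariant under swaps
    fac_names <- names(facs)
    key <- .grid_key(cand)
    iter <- 0
    while (anyDuplicated(key) > 0) {
      iter <- iter + 1
      if (iter > 5000) stopf("could not de-duplicate the stratified sample")
      for (i in which(duplicated(key))) {
        f <- sample(fac_names, 1)
        j <- sample.int(k, 1)
        flds <- if (f == "pa") c("pa_sessions", "pa_duration", "pa_intensity") else f
        tmp <- cand[i, flds]
        cand[i, flds] <- cand[j, flds]
        cand[j, flds] <- tmp
      }
      key <- .grid_key(cand)
    }
    idx <- match(key, .grid_key(grid))
    if (anyNA(idx)) {
      stopf("stratified sampling requires a full-factorial grid; use scheme = 'random'")
    }
    grid[sort(idx), , drop = FALSE]
  })
}

#' Split a design sample into training and test subjects
#'
#' Partitions a sample at the subject level (all 26 weeks of a subject end up
#' on the same side) with `floor(train_fraction * k)` training subjects.
#'
#' @param sample a `design_sample` from [lhs_sample()].
#' @param train_fraction proportion in (0, 1); the study default is 0.7.
#' @param seed integer seed for the shuffle.
#' @return A list with `design_sample` elements `train` and `test`.
#' @export
split_train_test <- function(sample, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  k <- nrow(sample)
  n_train <- floor(train_fraction * k)
  idx <- with_seed(derive_seed(seed, "split"), sample.int(k))
  take <- function(rows) {
    out <- sample[sort(rows), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "seed") <- as.integer(seed)
    attr(out, "scheme") <- attr(sample, "scheme")
    class(out) <- c("design_sample", "data.frame")
    out
  }
  list(train = take(idx[seq_len(n_train)]),
       test  = take(idx[setdiff(seq_len(k), seq_len(n_train))]))
}
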