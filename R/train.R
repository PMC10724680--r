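# CycleGAN training: identity pretraining, linearly decaying
# cycle-consistency weight, generated-image history buffer, mixed
# real/new-fake/old-fake discriminator batches, optional age-balanced
# sampling. Least-squares adversarial loss, Adam with the CycleGAN
# constants, generator batch size 1. All stochastic choices flow from one
# seeded RNG per run.

#' Training configuration
#'
#' @param total_steps number of adversarial training steps.
#' @param cycle_weight_start,cycle_weight_end endpoints of the linear
#'   cycle-consistency weight decay (200 to 100 over the run).
#' @param buffer_capacity capacity of the generated-image history buffer.
#' @param n_real,n_new_fake,n_old_fake discriminator batch composition.
#' @param gen_batch generator batch size (1).
#' @param learning_rate,beta1,beta2 Adam constants for the generators.
#' @param disc_learning_rate Adam learning rate for the discriminators
#'   (defaults to `learning_rate`).
#' @param seed run seed; every stochastic choice derives from it.
#' @param intensity_scale intensities are divided by this before entering
#'   the networks (brain median 500 maps to 1) and rescaled after.
#' @param mixed_precision must be `FALSE`: this implementation computes in
#'   double precision throughout.
#' @return an object of class `training_config`.
#' @export
training_config <- function(total_steps = 300L, cycle_weight_start = 200,
                            cycle_weight_end = 100, buffer_capacity = 50L,
                            n_real = 4L, n_new_fake = 2L, n_old_fake = 2L,
                            gen_batch = 1L, learning_rate = 2e-4,
                            disc_learning_rate = learning_rate,
                            beta1 = 0.5, beta2 = 0.999, seed = 1L,
                            intensity_scale = 500,
                            mixed_precision = FALSE) {
  if (!(cycle_weight_start >= cycle_weight_end && cycle_weight_end > 0))
    stop("need cycle_weight_start >= cycle_weight_end > 0")
  if (buffer_capacity < n_old_fake)
    stop("buffer_capacity must be >= n_old_fake")
  if (any(c(n_real, n_new_fake, n_old_fake) < 0))
    stop("discriminator batch components must be >= 0")
  if (isTRUE(mixed_precision))
    stop("mixed_precision is not available: computation is double precision")
  structure(list(total_steps = as.integer(total_steps),
                 cycle_weight_start = cycle_weight_start,
                 cycle_weight_end = cycle_weight_end,
                 buffer_capacity = as.integer(buffer_capacity),
                 n_real = as.integer(n_real),
                 n_new_fake = as.integer(n_new_fake),
                 n_old_fake = as.integer(n_old_fake),
                 gen_batch = as.integer(gen_batch),
                 learning_rate = learning_rate,
                 disc_learning_rate = disc_learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), intensity_scale = intensity_scale,
                 mixed_precision = FALSE), class = "training_config")
}

#' Linearly decaying cycle-consistency weight
#'
#' `start + (end - start) * step / total`: 200 at step 0, 100 at the final
#' step under the defaults.
#'
#' @param step current step (0-based, `0 <= step <= total`).
#' @param total total number of steps.
#' @param start,end schedule endpoints.
#' @return the weight at `step`.
#' @export
cycle_weight <- function(step, total, start = 200, end = 100) {
  if (total <= 0) stop("total must be positive")
  if (any(step < 0) || any(step > total))
    stop("step must lie in [0, total]")
  start + (end - start) * step / total
}

#' Generated-image history buffer
#'
#' Stores up to `capacity` previously generated images for discriminator
#' stabilization. [buffer_offer()] implements the classic store-or-swap
#' rule: below capacity the offer is stored and returned; at capacity,
#' with probability 1/2 the offer is returned unchanged, otherwise a
#' uniformly chosen stored image is returned and replaced by the offer.
#'
#' @param capacity maximum number of stored images.
#' @return an object of class `history_buffer` (environment-backed).
#' @export
history_buffer <- function(capacity = 50L) {
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$store <- vector("list", 0L)
  class(buf) <- "history_buffer"
  buf
}

#' @rdname history_buffer
#' @export
buffer_size <- function(buf) length(buf$store)

#' Offer an image to the history buffer
#'
#' @param buf a [history_buffer()].
#' @param image the newly generated image.
#' @return the image to show the discriminator (the offer or a swapped-out
#'   stored image); draws from the current RNG stream.
#' @export
buffer_offer <- function(buf, image) {
  if (length(buf$store) < buf$capacity) {
    buf$store[[length(buf$store) + 1L]] <- image
    return(image)
  }
  if (stats::runif(1) < 0.5) return(image)
  i <- sample.int(length(buf$store), 1L)
  old <- buf$store[[i]]
  buf$store[[i]] <- image
  old
}

# Draw n stored images uniformly (with replacement) from the buffer.
buffer_sample <- function(buf, n) {
  if (n == 0L || !length(buf$store)) return(list())
  buf$store[sample.int(length(buf$store), n, replace = TRUE)]
}

#' Compose a discriminator batch
#'
#' Builds the labelled batch one discriminator update consumes: `n_real`
#' real images, `n_new_fake` newly generated images and `n_old_fake`
#' history images under the defaults (4/2/2, total 8). When the buffer
#' holds fewer than `n_old_fake` images the shortfall is filled with
#' additional new fakes (recycling the new-fake pool if needed).
#'
#' @param reals list of real images (>= `n_real`).
#' @param new_fakes list of newly generated images (>= `n_new_fake`).
#' @param buf a [history_buffer()].
#' @param cfg a [training_config()].
#' @return list of `list(image, label, source)`, `label` 1 for real, 0 for
#'   fake; `source` one of `"real"`, `"new"`, `"history"`.
#' @export
compose_disc_batch <- function(reals, new_fakes, buf, cfg) {
  if (length(reals) < cfg$n_real)
    stop("need at least ", cfg$n_real, " real images")
  if (length(new_fakes) < cfg$n_new_fake)
    stop("need at least ", cfg$n_new_fake, " new fake images")
  r_idx <- sample.int(length(reals), cfg$n_real)
  hist <- buffer_sample(buf, min(cfg$n_old_fake, buffer_size(buf)))
  extra <- cfg$n_old_fake - length(hist)
  n_new <- cfg$n_new_fake + extra
  new_sel <- new_fakes[((seq_len(n_new) - 1L) %% length(new_fakes)) + 1L]
  c(lapply(reals[r_idx], function(im)
      list(image = im, label = 1, source = "real")),
    lapply(new_sel, function(im)
      list(image = im, label = 0, source = "new")),
    lapply(hist, function(im)
      list(image = im, label = 0, source = "history")))
}

#' Age-balanced sampling plan
#'
#' Assigns one shared per-age-bin sampling probability to two training
#' sets so that, at every step, both sites are sampled from the same age
#' distribution (protecting age effects from being confused with site
#' effects). The shared probability is proportional to
#' `min(n_A(bin), n_B(bin))` — zero whenever either site has an empty bin
#' — which maximizes use of the limiting site in each bin and avoids
#' undersampling the smallest populations. Within a bin, subjects are
#' drawn uniformly with replacement.
#'
#' @param agesA,agesB ages (years) of the two training sets.
#' @param bin_width age bin width in years.
#' @return an object of class `sampler_plan` with `edges`, `q` (per-bin
#'   probabilities summing to 1), and per-site within-bin index lists.
#' @export
age_balanced_plan <- function(agesA, agesB, bin_width = 10) {
  stopifnot(length(agesA) >= 1L, length(agesB) >= 1L)
  lo <- floor(min(agesA, agesB) / bin_width) * bin_width
  hi <- ceiling(max(agesA, agesB) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L
  binA <- findInterval(agesA, edges, rightmost.closed = TRUE)
  binB <- findInterval(agesB, edges, rightmost.closed = TRUE)
  nA <- tabulate(binA, nb)
  nB <- tabulate(binB, nb)
  q <- pmin(nA, nB)
  if (all(q == 0)) stop("degenerate input: no age bin populated in both sets")
  q <- q / sum(q)
  structure(list(edges = edges, q = q,
                 idxA = lapply(seq_len(nb), function(b) which(binA == b)),
                 idxB = lapply(seq_len(nb), function(b) which(binB == b))),
            class = "sampler_plan")
}

#' Draw subject indices from a sampling plan
#'
#' @param plan a [age_balanced_plan()].
#' @param site `"A"` or `"B"`.
#' @param n number of draws.
#' @return integer indices into the site's age list; draws use the current
#'   RNG stream.
#' @export
plan_sample <- function(plan, site = c("A", "B"), n = 1L) {
  site <- match.arg(site)
  idx <- if (site == "A") plan$idxA else plan$idxB
  bins <- sample.int(length(plan$q), n, replace = TRUE, prob = plan$q)
  vapply(bins, function(b) {
    pool <- idx[[b]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
}

# Internal: extract scaled training arrays from a cohort.
training_set <- function(cohort, intensity_scale) {
  lapply(cohort$phantoms, function(ph)
    list(x = ph$volume$data / intensity_scale, m = ph$volume$mask,
         age = ph$age))
}

l1_loss_grad <- function(out, target) {
  n <- length(out)
  diff <- out - target
  list(loss = mean(abs(diff)), grad = array(sign(diff) / n, dim = dim(out)))
}

#' Identity pretraining
#'
#' Trains a generator to replicate its (masked) input with an L1 loss over
#' all supplied volumes pooled across sites; both CycleGAN generators are
#' then initialized from the result.
#'
#' @param gen a [build_generator()] object.
#' @param vols list of [volume()]s (median-normalized).
#' @param steps optimization steps (batch size 1).
#' @param learning_rate,beta1,beta2 Adam constants.
#' @param intensity_scale network intensity scale (see
#'   [training_config()]).
#' @param seed RNG seed for volume sampling.
#' @return list with the pretrained `gen` and the L1 `trace` (one entry
#'   per step).
#' @export
pretrain_identity <- function(gen, vols, steps = 200L, learning_rate = 2e-4,
                              beta1 = 0.5, beta2 = 0.999,
                              intensity_scale = 500, seed = 1L) {
  stopifnot(length(vols) >= 1L)
  xs <- lapply(vols, function(v) list(x = v$data / intensity_scale,
                                      m = v$mask))
  with_seed(seed, {
    opt <- adam_init(gen$params)
    trace <- numeric(steps)
    for (s in seq_len(steps)) {
      it <- xs[[sample.int(length(xs), 1L)]]
      fw <- generator_forward(gen, it$x, keep_cache = TRUE)
      out <- fw$out * it$m
      lg <- l1_loss_grad(out, it$x)
      trace[s] <- lg$loss
      bw <- generator_backward(gen, fw$cache, lg$grad * it$m)
      upd <- adam_step(gen$params, bw$grads, opt, learning_rate, beta1, beta2)
      gen$params <- upd$params
      opt <- upd$state
    }
    list(gen = gen, trace = trace)
  })
}

# LSGAN patch loss pieces: mean squared deviation of the patch map from
# the target, and its gradient.
lsgan_loss_grad <- function(dmap, target) {
  n <- length(dmap)
  diff <- dmap - target
  list(loss = mean(diff^2), grad = array(2 * diff / n, dim = dim(dmap)))
}

#' Train a two-site CycleGAN
#'
#' Two generators (A to B and B to A) and two patchGAN discriminators
#' trained with the least-squares adversarial loss plus an L1
#' cycle-consistency loss weighted by [cycle_weight()]. Generators are
#' updated with batch size 1; each discriminator is updated with a batch
#' from [compose_disc_batch()] (4 real / 2 new fake / 2 history fake under
#' the defaults). Generation is always masked. Aborts with a diagnostic
#' dump if any loss becomes non-finite.
#'
#' @param cohortA,cohortB `cohort` objects, volumes median-normalized and
#'   with dimensions divisible by `2^depth`.
#' @param cfg a [training_config()].
#' @param plan optional [age_balanced_plan()] built from the two cohorts'
#'   ages; `NULL` samples uniformly.
#' @param gen_spec,disc_spec network specifications.
#' @param init_gen optional pretrained generator whose weights initialize
#'   both generators (see [pretrain_identity()]).
#' @return list with generators `G_AB`, `G_BA`, discriminators `D_A`,
#'   `D_B`, the per-step loss `trace` (data.frame), and `cfg`.
#' @export
train_cyclegan <- function(cohortA, cohortB, cfg = training_config(),
                           plan = NULL, gen_spec = generator_spec(),
                           disc_spec = discriminator_spec(),
                           init_gen = NULL) {
  A <- training_set(cohortA, cfg$intensity_scale)
  B <- training_set(cohortB, cfg$intensity_scale)
  stopifnot(length(A) >= cfg$n_real, length(B) >= cfg$n_real)
  with_seed(cfg$seed, {
    G_AB <- if (is.null(init_gen)) build_generator(gen_spec) else init_gen
    G_BA <- if (is.null(init_gen)) build_generator(gen_spec) else init_gen
    D_A <- build_discriminator(disc_spec)
    D_B <- build_discriminator(disc_spec)
    opt_gab <- adam_init(G_AB$params)
    opt_gba <- adam_init(G_BA$params)
    opt_da <- adam_init(D_A$params)
    opt_db <- adam_init(D_B$params)
    buf_A <- history_buffer(cfg$buffer_capacity)   # fake-A history
    buf_B <- history_buffer(cfg$buffer_capacity)   # fake-B history
    tr <- vector("list", cfg$total_steps)

    for (step in seq_len(cfg$total_steps)) {
      ia <- if (is.null(plan)) sample.int(length(A), 1L)
            else plan_sample(plan, "A", 1L)
      ib <- if (is.null(plan)) sample.int(length(B), 1L)
            else plan_sample(plan, "B", 1L)
      a <- A[[ia]]; b <- B[[ib]]
      lam <- cycle_weight(step - 1L, cfg$total_steps,
                          cfg$cycle_weight_start, cfg$cycle_weight_end)

      ## ---- generator update (batch 1 per direction) ----
      fbF <- generator_forward(G_AB, a$x, keep_cache = TRUE)
      fb <- fbF$out * a$m
      faF <- generator_forward(G_BA, b$x, keep_cache = TRUE)
      fa <- faF$out * b$m
      recaF <- generator_forward(G_BA, fb, keep_cache = TRUE)
      reca <- recaF$out * a$m
      recbF <- generator_forward(G_AB, fa, keep_cache = TRUE)
      recb <- recbF$out * b$m

      dbF <- discriminator_forward(D_B, fb, keep_cache = TRUE)
      advB <- lsgan_loss_grad(dbF$out, 1)
      d_fb_adv <- array(discriminator_backward(D_B, dbF$cache,
                                               advB$grad)$dx,
                        dim = dim(fb))
      daF <- discriminator_forward(D_A, fa, keep_cache = TRUE)
      advA <- lsgan_loss_grad(daF$out, 1)
      d_fa_adv <- array(discriminator_backward(D_A, daF$cache,
                                               advA$grad)$dx,
                        dim = dim(fa))

      cycA <- l1_loss_grad(reca, a$x)
      bw_cyc_a <- generator_backward(G_BA, recaF$cache,
                                     lam * cycA$grad * a$m)
      cycB <- l1_loss_grad(recb, b$x)
      bw_cyc_b <- generator_backward(G_AB, recbF$cache,
                                     lam * cycB$grad * b$m)

      d_fb <- (d_fb_adv + array(bw_cyc_a$dx, dim = dim(fb))) * a$m
      bw_ab <- generator_backward(G_AB, fbF$cache, d_fb)
      d_fa <- (d_fa_adv + array(bw_cyc_b$dx, dim = dim(fa))) * b$m
      bw_ba <- generator_backward(G_BA, faF$cache, d_fa)

      g_ab <- add_grads(bw_ab$grads, bw_cyc_b$grads)
      g_ba <- add_grads(bw_ba$grads, bw_cyc_a$grads)
      upd <- adam_step(G_AB$params, g_ab, opt_gab, cfg$learning_rate,
                       cfg$beta1, cfg$beta2)
      G_AB$params <- upd$params; opt_gab <- upd$state
      upd <- adam_step(G_BA$params, g_ba, opt_gba, cfg$learning_rate,
                       cfg$beta1, cfg$beta2)
      G_BA$params <- upd$params; opt_gba <- upd$state

      ## ---- discriminator updates ----
      need_extra <- function(buf) max(0L, cfg$n_old_fake - buffer_size(buf))
      gen_fake <- function(G, pool, plan_site) {
        i <- if (is.null(plan)) sample.int(length(pool), 1L)
             else plan_sample(plan, plan_site, 1L)
        it <- pool[[i]]
        generator_forward(G, it$x)$out * it$m
      }
      fakes_B <- c(list(fb),
                   replicate(cfg$n_new_fake - 1L + need_extra(buf_B),
                             gen_fake(G_AB, A, "A"), simplify = FALSE))
      fakes_A <- c(list(fa),
                   replicate(cfg$n_new_fake - 1L + need_extra(buf_A),
                             gen_fake(G_BA, B, "B"), simplify = FALSE))

      upd_disc <- function(D, opt, batch) {
        grads <- NULL
        loss <- 0
        for (it in batch) {
          fw <- discriminator_forward(D, it$image, keep_cache = TRUE)
          lg <- lsgan_loss_grad(fw$out, it$label)
          loss <- loss + lg$loss / length(batch)
          bw <- discriminator_backward(D, fw$cache,
                                       lg$grad / length(batch))
          grads <- add_grads(grads, bw$grads)
        }
        upd <- adam_step(D$params, grads, opt, cfg$disc_learning_rate,
                         cfg$beta1, cfg$beta2)
        list(D = {
          D$params <- upd$params; D
        }, opt = upd$state, loss = loss)
      }
      batch_B <- compose_disc_batch(lapply(B, `[[`, "x"), fakes_B, buf_B, cfg)
      rB <- upd_disc(D_B, opt_db, batch_B)
      D_B <- rB$D; opt_db <- rB$opt
      batch_A <- compose_disc_batch(lapply(A, `[[`, "x"), fakes_A, buf_A, cfg)
      rA <- upd_disc(D_A, opt_da, batch_A)
      D_A <- rA$D; opt_da <- rA$opt
      for (f in fakes_B) buffer_offer(buf_B, f)
      for (f in fakes_A) buffer_offer(buf_A, f)

      row <- data.frame(step = step, lambda = lam, idx_a = ia, idx_b = ib,
                        g_adv_ab = advB$loss, g_adv_ba = advA$loss,
                        cycle_a = cycA$loss, cycle_b = cycB$loss,
                        d_a = rA$loss, d_b = rB$loss)
      if (!all(is.finite(unlist(row)))) {
        dump <- tempfile("cyclegan_diag_", fileext = ".rds")
        saveRDS(list(step = step, row = row, G_AB = G_AB, G_BA = G_BA),
                dump)
        stop("non-finite loss at step ", step, "; state dumped to ", dump)
      }
      tr[[step]] <- row
    }
    list(G_AB = G_AB, G_BA = G_BA, D_A = D_A, D_B = D_B,
         trace = do.call(rbind, tr), cfg = cfg)
  })
}

#' Harmonize one volume with a trained generator
#'
#' Scales intensities into the network domain, applies masked generation
#' and scales back.
#'
#' @param gen a trained generator.
#' @param vol a [volume()] with a mask.
#' @param intensity_scale the scale the generator was trained with.
#' @return a [volume()].
#' @export
harmonize_volume <- function(gen, vol, intensity_scale = 500) {
  scaled <- volume(vol$data / intensity_scale, mask = vol$mask,
                   spacing = vol$spacing, affine = vol$affine)
  out <- masked_generate(gen, scaled)
  volume(out$data * intensity_scale, mask = vol$mask,
         spacing = vol$spacing, affine = vol$affine)
}
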