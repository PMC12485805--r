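# Peak-mean distribution families (the "generalized gamma" family menu):
# maximum-likelihood fitting and random generation. Weibull and gamma go
# through fitdistrplus with method-of-moments starts; lognormal and Pareto
# have closed-form MLEs; the lognormal-gamma mixture uses a small EM.

.checkFamily <- function(family) {
    if (!is.character(family) || length(family) != 1 ||
        !family %in% .peakFamilies)
        stop("unknown peak-mean family '", paste(family, collapse = ","),
             "'; supported: ", paste(.peakFamilies, collapse = ", "),
             call. = FALSE)
    family
}

# Weibull shape start from the CV (standard power-law approximation),
# scale from the mean
.weibullStart <- function(x) {
    cv <- stats::sd(x) / mean(x)
    shape <- max(0.05, cv^(-1.086))
    list(shape = shape, scale = mean(x) / gamma(1 + 1 / shape))
}

.fitFamily <- function(x, family) {
    family <- .checkFamily(family)
    x <- x[is.finite(x)]
    if (any(x <= 0))
        stop("family fitting requires strictly positive values",
             call. = FALSE)
    if (length(x) < 3)
        stop("need at least 3 values to fit a distribution", call. = FALSE)
    if (stats::sd(x) == 0)
        stop("degenerate input: values are constant, cannot fit family '",
             family, "'", call. = FALSE)
    fit <- switch(family,
        weibull = {
            f <- tryCatch(
                fitdistrplus::fitdist(x, "weibull",
                    start = .weibullStart(x),
                    control = list(reltol = 1e-8)),
                error = function(e) stop(
                    "Weibull fit failed to converge: ", conditionMessage(e),
                    call. = FALSE))
            list(shape = unname(f$estimate["shape"]),
                 scale = unname(f$estimate["scale"]), extra = list())
        },
        gamma = {
            m <- mean(x); v <- stats::var(x)
            f <- tryCatch(
                fitdistrplus::fitdist(x, "gamma",
                    start = list(shape = m^2 / v, rate = m / v),
                    control = list(reltol = 1e-8)),
                error = function(e) stop(
                    "gamma fit failed to converge: ", conditionMessage(e),
                    call. = FALSE))
            list(shape = unname(f$estimate["shape"]),
                 scale = 1 / unname(f$estimate["rate"]), extra = list())
        },
        lnorm = {
            ml <- mean(log(x)); sl <- sqrt(mean((log(x) - ml)^2))
            list(shape = sl, scale = exp(ml),
                 extra = list(meanlog = ml, sdlog = sl))
        },
        pareto = {
            xm <- min(x)
            alpha <- length(x) / sum(log(x / xm))
            list(shape = alpha, scale = xm, extra = list())
        },
        lngamma = .fitLnormGammaMix(x))
    c(list(family = family), fit)
}

# EM for a 2-component lognormal + gamma mixture; the gamma M-step uses
# weighted method of moments (an ECM-style approximation, adequate for a
# unimodal-plus-tail peak-mean shape)
.fitLnormGammaMix <- function(x, maxIter = 200, tol = 1e-8) {
    w <- 0.5
    ml <- mean(log(x)); sl <- max(stats::sd(log(x)), 1e-3)
    m <- mean(x); v <- max(stats::var(x), 1e-12)
    sh <- m^2 / v; ra <- m / v
    ll0 <- -Inf
    for (it in seq_len(maxIter)) {
        d1 <- w * stats::dlnorm(x, ml, sl)
        d2 <- (1 - w) * stats::dgamma(x, shape = sh, rate = ra)
        tot <- pmax(d1 + d2, .Machine$double.xmin)
        r <- d1 / tot
        w <- min(max(mean(r), 1e-6), 1 - 1e-6)
        sr <- sum(r)
        ml <- sum(r * log(x)) / sr
        sl <- max(sqrt(sum(r * (log(x) - ml)^2) / sr), 1e-6)
        s1 <- sum(1 - r)
        wm <- sum((1 - r) * x) / s1
        wv <- max(sum((1 - r) * (x - wm)^2) / s1, 1e-12)
        sh <- wm^2 / wv; ra <- wm / wv
        ll <- sum(log(tot))
        if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) break
        ll0 <- ll
    }
    list(shape = sh, scale = 1 / ra,
         extra = list(weight = w, meanlog = ml, sdlog = sl))
}

.sampleFamily <- function(n, family, shape, scale, extra = list()) {
    family <- .checkFamily(family)
    switch(family,
        weibull = stats::rweibull(n, shape = shape, scale = scale),
        gamma = stats::rgamma(n, shape = shape, scale = scale),
        lnorm = stats::rlnorm(n, meanlog = extra$meanlog %||% log(scale),
                              sdlog = extra$sdlog %||% shape),
        pareto = scale * stats::runif(n)^(-1 / shape),
        lngamma = {
            w <- extra$weight %||% 0.5
            isLn <- stats::runif(n) < w
            out <- numeric(n)
            out[isLn] <- stats::rlnorm(sum(isLn),
                meanlog = extra$meanlog %||% 0,
                sdlog = extra$sdlog %||% 1)
            out[!isLn] <- stats::rgamma(sum(!isLn), shape = shape,
                                        scale = scale)
            out
        })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
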