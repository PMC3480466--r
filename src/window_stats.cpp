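#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static double median_of(std::vector<double> &buf) {
    const size_t n = buf.size();
    const size_t h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
        // lower middle: largest element below position h
        double lo = *std::max_element(buf.begin(), buf.begin() + h);
        m = (m + lo) / 2.0;
    }
    return m;
}

// Per-window median, sample SD and dynamic-activity magnitude.
//
// x:    n x nc matrix of raw samples (columns = channels, values in g)
// win:  window length in samples
// step: hop in samples
//
// activity = mean over the window's samples of
//            sqrt(sum over channels of (sample - channel median)^2),
// i.e. the mean magnitude of the median-subtracted (dynamic) acceleration.
// [[Rcpp::export]]
List window_stats_cpp(NumericMatrix x, int win, int step) {
    const int n = x.nrow(), nc = x.ncol();
    if (win < 2) stop("window must span at least 2 samples");
    if (nc < 1 || nc > 64) stop("1..64 channels supported");
    if (step < 1) stop("step must be positive");
    const int m = (n >= win) ? (n - win) / step + 1 : 0;

    NumericMatrix med(m, nc), sd(m, nc);
    NumericVector act(m);
    std::vector<double> buf(win);

    for (int w = 0; w < m; ++w) {
        const int off = w * step;
        double medians[64];
        for (int c = 0; c < nc; ++c) {
            const double *col = &x(0, c);
            double s = 0.0;
            for (int i = 0; i < win; ++i) {
                buf[i] = col[off + i];
                s += buf[i];
            }
            const double mean = s / win;
            double ss = 0.0;
            for (int i = 0; i < win; ++i) {
                const double d = buf[i] - mean;
                ss += d * d;
            }
            sd(w, c) = std::sqrt(ss / (win - 1));
            medians[c] = median_of(buf);
            med(w, c) = medians[c];
        }
        double a = 0.0;
        for (int i = 0; i < win; ++i) {
            double s2 = 0.0;
            for (int c = 0; c < nc; ++c) {
                const double d = x(off + i, c) - medians[c];
                s2 += d * d;
            }
            a += std::sqrt(s2);
        }
        act[w] = a / win;
    }
    return List::create(_["median"] = med, _["sd"] = sd, _["activity"] = act);
}
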