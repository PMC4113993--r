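#include <Rcpp.h>
using namespace Rcpp;

// Two spheres driven along coplanar circular orbits and coupled through the
// Oseen tensor. All forces are carried as reduced forces G = F/(8 pi mu) in
// um^2/s, so the Oseen contribution of sphere j at sphere i is
//   u = (G_j + (rhat.G_j) rhat) / r,     r = x_i - x_j,
// and the self term is F/(6 pi mu a) = (4/(3a)) G. The driving force is
// tangential with G_drive = A0 (1 + A1 sin(nu*phi + phi0)); the radial
// spring contributes -lam_red (r - r0) rhat with lam_red = lambda/(8 pi mu).
// lambda = Inf (rigid orbits) is treated as a holonomic constraint: radial
// reaction forces N_i are solved from a 2x2 linear system so that the radial
// velocity of each sphere vanishes exactly.

struct RowerSys {
    double cx[2];        // orbit centre x-coordinates (centres on the x axis)
    double a, r0, A0, A1, phi0, lam_red;
    int nu;
    bool rigid;

    void deriv(const double s[4], double ds[4]) const {
        double e[2][2], tg[2][2], x[2][2], Gd[2];
        for (int i = 0; i < 2; ++i) {
            double c = std::cos(s[i]), sn = std::sin(s[i]);
            double ri = rigid ? r0 : s[2 + i];
            e[i][0] = c;  e[i][1] = sn;
            tg[i][0] = -sn; tg[i][1] = c;
            x[i][0] = cx[i] + ri * c;
            x[i][1] = ri * sn;
            Gd[i] = A0 * (1.0 + A1 * std::sin(nu * s[i] + phi0));
        }
        double rv[2], rn, rh[2];
        rv[0] = x[0][0] - x[1][0];
        rv[1] = x[0][1] - x[1][1];
        rn = std::sqrt(rv[0] * rv[0] + rv[1] * rv[1]);
        rh[0] = rv[0] / rn; rh[1] = rv[1] / rn;
        double self = 4.0 / (3.0 * a);

        double N[2] = {0.0, 0.0};
        if (rigid) {
            // solve for radial reaction forces: v_i . e_i = 0
            // (4/(3a)) N_i + e_i.O.(Gd_j t_j) + (e_i.O.e_j) N_j = 0
            double b[2], m01[2];
            for (int i = 0; i < 2; ++i) {
                int j = 1 - i;
                double gj[2] = {Gd[j] * tg[j][0], Gd[j] * tg[j][1]};
                double rg = rh[0] * gj[0] + rh[1] * gj[1];
                double og[2] = {(gj[0] + rg * rh[0]) / rn,
                                (gj[1] + rg * rh[1]) / rn};
                b[i] = e[i][0] * og[0] + e[i][1] * og[1];
                double rej = rh[0] * e[j][0] + rh[1] * e[j][1];
                double oe[2] = {(e[j][0] + rej * rh[0]) / rn,
                                (e[j][1] + rej * rh[1]) / rn};
                m01[i] = e[i][0] * oe[0] + e[i][1] * oe[1];
            }
            double det = self * self - m01[0] * m01[1];
            N[0] = (-self * b[0] + m01[0] * b[1]) / det;
            N[1] = (-self * b[1] + m01[1] * b[0]) / det;
        }

        double G[2][2];
        for (int i = 0; i < 2; ++i) {
            double fr = rigid ? N[i] : -lam_red * (s[2 + i] - r0);
            G[i][0] = Gd[i] * tg[i][0] + fr * e[i][0];
            G[i][1] = Gd[i] * tg[i][1] + fr * e[i][1];
        }
        for (int i = 0; i < 2; ++i) {
            int j = 1 - i;
            double rg = rh[0] * G[j][0] + rh[1] * G[j][1];
            double v[2];
            v[0] = self * G[i][0] + (G[j][0] + rg * rh[0]) / rn;
            v[1] = self * G[i][1] + (G[j][1] + rg * rh[1]) / rn;
            double ri = rigid ? r0 : s[2 + i];
            ds[i] = (v[0] * tg[i][0] + v[1] * tg[i][1]) / ri;
            ds[2 + i] = rigid ? 0.0 : (v[0] * e[i][0] + v[1] * e[i][1]);
        }
    }
};

// [[Rcpp::export]]
List rower_rk4_cpp(NumericVector state0, double a, double r0, double d,
                   double A0, double A1, int nu, double phi0,
                   double lam_red, bool rigid, double dt, int nsteps,
                   int thin) {
    RowerSys sys;
    sys.cx[0] = -d / 2.0; sys.cx[1] = d / 2.0;
    sys.a = a; sys.r0 = r0; sys.A0 = A0; sys.A1 = A1;
    sys.phi0 = phi0; sys.nu = nu; sys.lam_red = lam_red; sys.rigid = rigid;

    double s[4] = {state0[0], state0[1], state0[2], state0[3]};
    int nout = nsteps / thin + 1;
    NumericVector t(nout), p1(nout), p2(nout), r1(nout), r2(nout);
    t[0] = 0; p1[0] = s[0]; p2[0] = s[1]; r1[0] = s[2]; r2[0] = s[3];
    int k = 1;
    double k1[4], k2[4], k3[4], k4[4], tmp[4];
    for (int i = 1; i <= nsteps; ++i) {
        sys.deriv(s, k1);
        for (int q = 0; q < 4; ++q) tmp[q] = s[q] + 0.5 * dt * k1[q];
        sys.deriv(tmp, k2);
        for (int q = 0; q < 4; ++q) tmp[q] = s[q] + 0.5 * dt * k2[q];
        sys.deriv(tmp, k3);
        for (int q = 0; q < 4; ++q) tmp[q] = s[q] + dt * k3[q];
        sys.deriv(tmp, k4);
        for (int q = 0; q < 4; ++q)
            s[q] += dt / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
        if (i % thin == 0 && k < nout) {
            t[k] = i * dt; p1[k] = s[0]; p2[k] = s[1];
            r1[k] = s[2]; r2[k] = s[3];
            ++k;
        }
        if (i % 97 == 0) {  // prime interval so the check never aliases
                            // with the orbital period
            double x1 = sys.cx[0] + s[2] * std::cos(s[0]);
            double y1 = s[2] * std::sin(s[0]);
            double x2 = sys.cx[1] + s[3] * std::cos(s[1]);
            double y2 = s[3] * std::sin(s[1]);
            double dist = std::hypot(x1 - x2, y1 - y2);
            if (dist < 2.0 * a)
                stop("spheres overlap during the run (separation %.3g um)",
                     dist);
        }
    }
    return List::create(_["t"] = t, _["phi1"] = p1, _["phi2"] = p2,
                        _["r1"] = r1, _["r2"] = r2);
}
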