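#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One vision region: squared radius plus optional front/back blind cones.
// Blind cones are full apex angles centred on +v (front) and -v (back);
// a neighbour is excluded when the cosine of its bearing from the heading
// exceeds cos(front/2) or falls below -cos(back/2).
struct Region {
  double r2;
  bool has_front, has_back;
  double cf, cb;
  Region(NumericVector spec) {
    double r = spec[0];
    r2 = r * r;
    has_front = spec[1] > 0.0;
    has_back  = spec[2] > 0.0;
    cf = has_front ? std::cos(spec[1] * M_PI / 360.0) : 2.0;
    cb = has_back  ? std::cos(spec[2] * M_PI / 360.0) : 2.0;
  }
  // dot = cosine of bearing; have_heading false when the focal fish is at
  // rest, in which case blind cones do not apply.
  bool sees(double d2, double dot, bool have_heading) const {
    if (d2 > r2) return false;
    if (!have_heading) return true;
    if (has_front && dot > cf) return false;
    if (has_back && dot < -cb) return false;
    return true;
  }
};

// Advance a school of flashing fish n_frames steps with synchronous
// explicit Euler integration. All force evaluations for frame s use only
// the state of frame s-1. Flash redraws consume R's RNG stream, one
// uniform per agent per frame in agent order (bernoulli mode only), so
// results are bitwise reproducible against the pure-R reference step.
// [[Rcpp::export]]
List sim_run_cpp(NumericMatrix pos0, NumericMatrix vel0,
                 LogicalVector dark, LogicalVector flash0,
                 LogicalVector motivated, NumericMatrix mot_vel,
                 IntegerVector phase, int on_frames, int period_frames,
                 int flash_mode, double P,
                 double wc, double wa, double ws, double wf, double wv,
                 double vmax, double vcruise, double dt,
                 NumericVector coh_spec, NumericVector ali_spec,
                 NumericVector sep_spec,
                 bool gate_all, int n_frames, int frame0) {
  const int n = pos0.nrow();
  Region coh(coh_spec), ali(ali_spec), sep(sep_spec);

  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  std::vector<int> fl(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
    fl[i] = flash0[i] ? 1 : 0;
  }

  const int T = n_frames + 1;
  NumericVector out_pos(n * 3 * T), out_vel(n * 3 * T);
  LogicalVector out_fl(n * T);
  out_pos.attr("dim") = IntegerVector::create(n, 3, T);
  out_vel.attr("dim") = IntegerVector::create(n, 3, T);
  out_fl.attr("dim") = IntegerVector::create(n, T);
  auto rec = [&](int s) {
    for (int i = 0; i < n; ++i) {
      out_pos[i + 0 * n + s * 3 * n] = px[i];
      out_pos[i + 1 * n + s * 3 * n] = py[i];
      out_pos[i + 2 * n + s * 3 * n] = pz[i];
      out_vel[i + 0 * n + s * 3 * n] = vx[i];
      out_vel[i + 1 * n + s * 3 * n] = vy[i];
      out_vel[i + 2 * n + s * 3 * n] = vz[i];
      out_fl[i + s * n] = fl[i] != 0;
    }
  };
  rec(0);

  std::vector<double> npx(n), npy(n), npz(n), nvx(n), nvy(n), nvz(n);

  for (int s = 1; s <= n_frames; ++s) {
    for (int i = 0; i < n; ++i) {
      double nx, ny, nz;
      if (motivated[i]) {
        nx = mot_vel(i, 0); ny = mot_vel(i, 1); nz = mot_vel(i, 2);
      } else {
        const double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] +
                                    vz[i] * vz[i]);
        const bool heading = sp > 0.0;
        const double hx = heading ? vx[i] / sp : 0.0;
        const double hy = heading ? vy[i] / sp : 0.0;
        const double hz = heading ? vz[i] / sp : 0.0;

        double ccx = 0, ccy = 0, ccz = 0; int cn = 0;
        double aax = 0, aay = 0, aaz = 0; int an = 0;
        double ssx = 0, ssy = 0, ssz = 0; int sn = 0;

        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          const double dx = px[j] - px[i];
          const double dy = py[j] - py[i];
          const double dz = pz[j] - pz[i];
          const double d2 = dx * dx + dy * dy + dz * dz;
          const bool vis = fl[j] != 0;          // flashing last frame
          if (d2 == 0.0) {
            // coincident agents are degenerate only when perceivable;
            // a pair of mutually invisible (gated, non-flashing) fish
            // simply does not interact
            if (vis || !gate_all)
              stop("degenerate geometry: coincident agents");
            continue;
          }
          const double dot = heading
            ? (dx * hx + dy * hy + dz * hz) / std::sqrt(d2) : 0.0;
          if (vis && coh.sees(d2, dot, heading)) {
            ccx += dx; ccy += dy; ccz += dz; ++cn;
          }
          if ((vis || !gate_all) && ali.sees(d2, dot, heading)) {
            aax += vx[j]; aay += vy[j]; aaz += vz[j]; ++an;
          }
          if ((vis || !gate_all) && sep.sees(d2, dot, heading)) {
            ssx -= dx / d2; ssy -= dy / d2; ssz -= dz / d2; ++sn;
          }
        }

        double fx = 0, fy = 0, fz = 0;
        // social forces: f = unit(s) * vmax - v; zero s-vector or empty
        // neighbour set contributes nothing
        if (cn > 0) {
          double sx = ccx / cn, sy = ccy / cn, sz = ccz / cn;
          double nm = std::sqrt(sx * sx + sy * sy + sz * sz);
          if (nm > 0) {
            fx += wc * (sx / nm * vmax - vx[i]);
            fy += wc * (sy / nm * vmax - vy[i]);
            fz += wc * (sz / nm * vmax - vz[i]);
          }
        }
        if (an > 0) {
          double sx = aax / an, sy = aay / an, sz = aaz / an;
          double nm = std::sqrt(sx * sx + sy * sy + sz * sz);
          if (nm > 0) {
            fx += wa * (sx / nm * vmax - vx[i]);
            fy += wa * (sy / nm * vmax - vy[i]);
            fz += wa * (sz / nm * vmax - vz[i]);
          }
        }
        if (sn > 0) {
          double sx = ssx / sn, sy = ssy / sn, sz = ssz / sn;
          double nm = std::sqrt(sx * sx + sy * sy + sz * sz);
          if (nm > 0) {
            fx += ws * (sx / nm * vmax - vx[i]);
            fy += ws * (sy / nm * vmax - vy[i]);
            fz += ws * (sz / nm * vmax - vz[i]);
          }
        }
        // friction (linear drag) and speed control toward v_cruise
        fx -= wf * vx[i]; fy -= wf * vy[i]; fz -= wf * vz[i];
        if (heading) {
          const double g = wv * (vcruise - sp);
          fx += g * hx; fy += g * hy; fz += g * hz;
        }

        nx = vx[i] + fx * dt;
        ny = vy[i] + fy * dt;
        nz = vz[i] + fz * dt;
        const double ns = std::sqrt(nx * nx + ny * ny + nz * nz);
        if (ns > vmax) {
          nx *= vmax / ns; ny *= vmax / ns; nz *= vmax / ns;
        }
      }
      if (!std::isfinite(nx) || !std::isfinite(ny) || !std::isfinite(nz))
        stop("numeric failure: non-finite velocity");
      nvx[i] = nx; nvy[i] = ny; nvz[i] = nz;
      npx[i] = px[i] + nx * dt;
      npy[i] = py[i] + ny * dt;
      npz[i] = pz[i] + nz * dt;
    }
    px.swap(npx); py.swap(npy); pz.swap(npz);
    vx.swap(nvx); vy.swap(nvy); vz.swap(nvz);

    if (flash_mode == 0) {            // bernoulli
      for (int i = 0; i < n; ++i) {
        const double u = unif_rand();
        fl[i] = (u < P && !dark[i]) ? 1 : 0;
      }
    } else {                          // square wave, phase in frames
      const int g = frame0 + s;
      for (int i = 0; i < n; ++i) {
        const int ph = ((g + phase[i]) % period_frames + period_frames) %
                       period_frames;
        fl[i] = (!dark[i] && ph < on_frames) ? 1 : 0;
      }
    }
    rec(s);
  }

  return List::create(_["position"] = out_pos, _["velocity"] = out_vel,
                      _["flashing"] = out_fl);
}
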