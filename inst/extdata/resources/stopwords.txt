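a
an
and
as
at
be
been
by
due
for
from
in
is
nos
not
of
on
or
other
the
to
unspecified
was
were
with
without
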