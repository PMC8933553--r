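# English stop words removed before lemmatization (one per line)
a
an
the
and
or
of
in
on
at
to
for
from
by
with
without
as
is
are
was
were
be
been
being
this
that
these
those
it
its
their
his
her
any
all
both
each
other
some
such
no
not
only
own
same
so
than
too
very
during
before
after
above
below
up
down
out
off
over
under
again
further
then
once
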