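a
about
above
after
again
against
all
also
am
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
did
do
doe
doing
down
during
each
few
for
from
further
had
ha
have
having
he
her
here
hers
herself
him
himself
his
how
i
if
in
into
is
it
its
itself
just
may
me
might
more
most
must
my
myself
no
nor
not
now
of
off
on
once
only
or
other
our
ours
ourselves
out
over
own
same
shall
she
should
so
some
such
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
under
until
up
upon
us
very
wa
we
were
what
when
where
which
while
who
whom
why
will
with
within
without
would
you
your
yours
yourself
yourselves
among
however
therefore
thus
via
per
et
al
eg
ie
etc
introduction
method
methodology
result
discussion
conclusion
background
objective
aim
purpose
abstract
paper
article
author
study
analysis
finding
data
research
copyright
license
licence
doi
preprint
elsevier
springer
wiley
journal
publisher
reserved
right
available
online
published
publication
version
figure
table
supplementary
appendix
section
keywords
keyword
was
has
does
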